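## Control-impact matching: each Tiger Reserve (impact) is paired with a
## Wildlife Sanctuary (control) of area >= 75 km2, in the same state, with
## long-term mean annual rainfall within 500 mm, at the shortest distance;
## conflicts are resolved with the next-nearest candidate.
##
## PA geometries are axis-aligned rectangles (xmin, ymin, xmax, ymax in
## projected metres), so area and separation are exact closed forms.

#' PA attribute table
#'
#' The matching functions operate on a plain `data.frame` with columns:
#' `id`, `name`, `status` (`"TR"`, `"WLS"` or `"other"`), `state`,
#' `area_km2` (> 0), `rainfall_mm` (long-term mean annual, >= 0),
#' `declaration_year` (integer; `NA` for non-TRs), and the rectangle
#' geometry `xmin`, `ymin`, `xmax`, `ymax` in projected metres.
#'
#' @name PATable
NULL

.pa_cols <- c("id", "name", "status", "state", "area_km2", "rainfall_mm",
              "declaration_year", "xmin", "ymin", "xmax", "ymax")

.check_pa_table <- function(table) {
  miss <- setdiff(.pa_cols, names(table))
  if (length(miss))
    stop("PA table lacks columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Separation distance between two PA rectangles
#'
#' Default metric is the minimum boundary-to-boundary separation (0 when the
#' rectangles touch or overlap); `"centroid"` gives the centroid-to-centroid
#' distance instead.
#'
#' @param a,b One-row PA records (anything with `xmin`, `ymin`, `xmax`,
#'   `ymax` in metres).
#' @param metric `"boundary"` (default) or `"centroid"`.
#' @return Distance in km.
#' @export
separationDistance <- function(a, b, metric = c("boundary", "centroid")) {
  metric <- match.arg(metric)
  if (a$xmin > a$xmax || a$ymin > a$ymax || b$xmin > b$xmax ||
      b$ymin > b$ymax)
    stop("invalid rectangle geometry")
  if (metric == "boundary") {
    dx <- max(0, a$xmin - b$xmax, b$xmin - a$xmax)
    dy <- max(0, a$ymin - b$ymax, b$ymin - a$ymax)
  } else {
    dx <- (a$xmin + a$xmax) / 2 - (b$xmin + b$xmax) / 2
    dy <- (a$ymin + a$ymax) / 2 - (b$ymin + b$ymax) / 2
  }
  sqrt(dx^2 + dy^2) / 1000
}

#' Area-weighted mean annual rainfall over a PA
#'
#' Sums the 12 monthly means of a gridded climatology into an annual total
#' per cell and averages those totals over the cells intersecting the PA
#' rectangle, weighting each cell by its overlap area.
#'
#' @param pa One-row PA record with rectangle geometry in metres.
#' @param grid List describing the monthly climatology: `monthly` a
#'   `nrow x ncol x 12` array of mm/month (row 1 at the grid's bottom edge),
#'   `origin` the lower-left corner `c(x, y)` in metres, `cellSize` the cell
#'   edge in metres.
#' @return Mean annual rainfall in mm/yr.
#' @export
paMeanRainfall <- function(pa, grid) {
  annual <- apply(grid$monthly, c(1, 2), sum)
  cs <- grid$cellSize
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  nr <- nrow(annual); nc <- ncol(annual)
  j0 <- max(1L, floor((pa$xmin - x0) / cs) + 1L)
  j1 <- min(nc, ceiling((pa$xmax - x0) / cs))
  i0 <- max(1L, floor((pa$ymin - y0) / cs) + 1L)
  i1 <- min(nr, ceiling((pa$ymax - y0) / cs))
  if (j0 > j1 || i0 > i1)
    stop("precipitation grid does not cover the PA")
  jr <- j0:j1
  ir <- i0:i1
  wsum <- 0; vsum <- 0
  for (i in ir) for (j in jr) {
    ox <- max(0, min(pa$xmax, x0 + j * cs) - max(pa$xmin, x0 + (j - 1) * cs))
    oy <- max(0, min(pa$ymax, y0 + i * cs) - max(pa$ymin, y0 + (i - 1) * cs))
    w <- ox * oy
    wsum <- wsum + w
    vsum <- vsum + w * annual[i, j]
  }
  if (wsum <= 0) stop("precipitation grid does not cover the PA")
  vsum / wsum
}

#' Candidate controls for one impact PA
#'
#' WLS-status records in the same state as the TR, with area at or above the
#' floor (inclusive, 75 km2 default) and mean annual rainfall within the
#' window (inclusive, 500 mm default) of the TR's.
#'
#' @param tr One-row TR record.
#' @param table A [PATable] `data.frame`.
#' @param config An [AnalysisConfig-class].
#' @return The qualifying rows of `table` (possibly zero rows).
#' @export
candidateWLS <- function(tr, table, config = analysisConfig()) {
  .check_pa_table(table)
  keep <- table$status == "WLS" &
    table$state == tr$state &
    table$area_km2 >= config@wlsMinArea &
    abs(table$rainfall_mm - tr$rainfall_mm) <= config@rainfallWindow
  table[keep, , drop = FALSE]
}

#' Match every TR with a distinct WLS
#'
#' Each TR takes its nearest candidate control (per [candidateWLS()] and
#' [separationDistance()]). TRs are processed in ascending declaration year,
#' then ascending id; when a TR's nearest candidate is already taken by an
#' earlier-processed TR it falls back to its next-nearest remaining
#' candidate, so the final assignment is injective on WLSs. TRs with no
#' remaining candidate are reported unmatched.
#'
#' @param table A [PATable] `data.frame`.
#' @param config An [AnalysisConfig-class].
#' @return List with `pairs` (a `data.frame`: `tr_id`, `wls_id`,
#'   `rainfall_difference_mm`, `separation_km`) and `unmatched` (TR ids).
#' @export
matchPairs <- function(table, config = analysisConfig()) {
  .check_pa_table(table)
  trs <- table[table$status == "TR", , drop = FALSE]
  trs <- trs[order(trs$declaration_year, trs$id), , drop = FALSE]
  taken <- character()
  pairs <- list()
  unmatched <- character()
  for (i in seq_len(nrow(trs))) {
    tr <- trs[i, , drop = FALSE]
    cand <- candidateWLS(tr, table, config)
    cand <- cand[!(cand$id %in% taken), , drop = FALSE]
    if (nrow(cand) == 0L) {
      unmatched <- c(unmatched, tr$id)
      next
    }
    d <- vapply(seq_len(nrow(cand)), function(j)
      separationDistance(tr, cand[j, , drop = FALSE],
                         config@distanceMetric), numeric(1))
    best <- order(d, cand$id)[1L]
    wls <- cand[best, , drop = FALSE]
    taken <- c(taken, wls$id)
    pairs[[length(pairs) + 1L]] <- data.frame(
      tr_id = tr$id, wls_id = wls$id,
      rainfall_difference_mm = abs(tr$rainfall_mm - wls$rainfall_mm),
      separation_km = d[best],
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(tr_id = character(), wls_id = character(),
                           rainfall_difference_mm = numeric(),
                           separation_km = numeric())
  list(pairs = pairs, unmatched = unmatched)
}
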