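## Epoch-wise robust trend estimation on the annual composite series.

#' Sen's slope of a time series
#'
#' Nonparametric robust slope. The default Theil-Sen form is the median of
#' all pairwise slopes `(y_j - y_i) / (x_j - x_i)`, `i < j`; the Siegel
#' repeated-medians form takes, for each point, the median of its pairwise
#' slopes with every other point, then the median of those. The median of an
#' even count is the mean of the two central values. Pairs with coincident
#' abscissae are dropped; if no pair remains the slope is undefined and an
#' error is raised.
#'
#' @param x Abscissae (here: composite date-stamps in fractional years).
#' @param y Ordinates (index values). `NA` pairs are dropped.
#' @param estimator `"theil-sen"` (default) or `"siegel"`.
#' @return The slope, in units of `y` per unit of `x`.
#' @examples
#' senSlope(0:4, 0:4)                 # collinear: 1
#' senSlope(0:3, c(0, 2, 1, 3))       # 0.75
#' @export
senSlope <- function(x, y, estimator = c("theil-sen", "siegel")) {
  estimator <- match.arg(estimator)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 points")
  dx <- outer(x, x, "-")
  if (estimator == "theil-sen") {
    s <- outer(y, y, "-") / dx
    s <- s[lower.tri(s) & is.finite(s)]
    if (length(s) == 0L) stop("undefined slope: all abscissae equal")
    stats::median(s)
  } else {
    s <- outer(y, y, "-") / dx
    med_i <- vapply(seq_len(n), function(i) {
      si <- s[i, -i]
      si <- si[is.finite(si)]
      if (length(si) == 0L) NA_real_ else stats::median(si)
    }, numeric(1))
    med_i <- med_i[!is.na(med_i)]
    if (length(med_i) == 0L) stop("undefined slope: all abscissae equal")
    stats::median(med_i)
  }
}

.epoch_ranges <- function(yearRange, declarationYear,
                          declarationEpoch = "after") {
  declarationYear <- as.integer(declarationYear)
  if (declarationYear < yearRange[1] || declarationYear > yearRange[2])
    stop("declaration year outside the composite year range")
  split <- if (declarationEpoch == "after") declarationYear
           else declarationYear + 1L
  before <- if (split - 1L >= yearRange[1]) c(yearRange[1], split - 1L)
  after <- if (split <= yearRange[2]) c(split, yearRange[2])
  list(before = before, after = after)
}

#' Pixel data-sufficiency within an epoch
#'
#' A pixel keeps its slope in an epoch only if it has at least `minPoints`
#' valid composite years there; a pixel with fewer is dropped from the
#' regression for insufficient data.
#'
#' @param series An [AnnualCompositeSeries-class].
#' @param epoch Inclusive year range `c(first, last)`.
#' @param track `"evi"` (brownest) or `"ndii"` (driest).
#' @param minPoints Validity threshold (default 5).
#' @return Logical vector over pixels: `TRUE` where sufficient.
#' @export
pixelValidity <- function(series, epoch, track = c("evi", "ndii"),
                          minPoints = 5L) {
  track <- match.arg(track)
  yrs <- compositeYears(series)
  if (epoch[1] < min(yrs) || epoch[2] > max(yrs))
    stop("epoch outside the series' year range")
  sel <- yrs >= epoch[1] & yrs <= epoch[2]
  v <- assay(series, track)[, sel, drop = FALSE]
  rowSums(!is.na(v)) >= minPoints
}

#' PA-level data sufficiency within an epoch
#'
#' A protected area is retained for analysis in an epoch only if at most
#' `maxInsufficientFraction` of its pixels are insufficient there; a PA with
#' more than that fraction insufficient is dropped from analyses involving
#' the epoch.
#'
#' @param validity Logical per-pixel sufficiency (from [pixelValidity()], or
#'   any per-pixel flag on the scene grid).
#' @param paMask Logical per-pixel PA membership on the same grid; must
#'   select at least one pixel.
#' @param maxInsufficientFraction Retention threshold (default 0.20).
#' @return `TRUE` (retained) or `FALSE` (dropped), with the insufficient
#'   fraction attached as attribute `"insufficientFraction"`.
#' @export
paSufficiency <- function(validity, paMask,
                          maxInsufficientFraction = 0.20) {
  if (length(validity) != length(paMask))
    stop("validity and paMask must be on the same grid")
  if (!any(paMask)) stop("empty PA mask")
  frac <- mean(!validity[paMask])
  structure(frac <= maxInsufficientFraction, insufficientFraction = frac)
}

#' Estimate per-pixel epoch-wise Sen's slopes
#'
#' Splits the composite series into before/after epochs at the declaration
#' year (the declaration year itself opening the `"after"` epoch by default)
#' and estimates, per pixel and per track, the Sen's slope of composite value
#' against composite date-stamp (fractional years, not integer years) within
#' each epoch. Pixels with fewer than `minPoints` valid composite years in an
#' epoch carry no slope there.
#'
#' @param composites An [AnnualCompositeSeries-class].
#' @param declarationYear Declaration year of the impact PA.
#' @param minPoints Per-pixel validity threshold (default 5).
#' @param estimator Passed to [senSlope()].
#' @param declarationEpoch `"after"` (default) or `"before"`: which epoch
#'   owns the declaration year.
#' @return A [SlopeMaps-class].
#' @export
estimateEpochSlopes <- function(composites, declarationYear,
                                minPoints = 5L,
                                estimator = c("theil-sen", "siegel"),
                                declarationEpoch = c("after", "before")) {
  estimator <- match.arg(estimator)
  declarationEpoch <- match.arg(declarationEpoch)
  minPoints <- as.integer(minPoints)
  yrs <- compositeYears(composites)
  epochs <- .epoch_ranges(range(yrs), declarationYear, declarationEpoch)
  npx <- nrow(composites)
  slopes <- matrix(NA_real_, npx, 4L,
                   dimnames = list(NULL, .slope_cols))
  nYears <- matrix(0L, npx, 4L, dimnames = list(NULL, .slope_cols))
  tracks <- c(b = "evi", d = "ndii")
  for (tk in names(tracks)) {
    val <- assay(composites, tracks[[tk]])
    tim <- assay(composites, paste0(tracks[[tk]], "Time"))
    for (ep in c("before", "after")) {
      colname <- paste(tk, ep, sep = "_")
      rng <- epochs[[ep]]
      if (is.null(rng)) next
      sel <- yrs >= rng[1] & yrs <= rng[2]
      v <- val[, sel, drop = FALSE]
      t <- tim[, sel, drop = FALSE]
      nv <- rowSums(!is.na(v))
      nYears[, colname] <- nv
      idx <- which(nv >= minPoints)
      for (i in idx)
        slopes[i, colname] <- senSlope(t[i, ], v[i, ], estimator)
    }
  }
  scene <- metadata(composites)$scene
  dim2 <- if (!is.null(scene)) c(scene@height, scene@width)
          else c(npx, 1L)
  new("SlopeMaps",
    slopes = slopes, nYears = nYears, epochs = epochs,
    declarationYear = as.integer(declarationYear),
    minPoints = minPoints, sceneDim = as.integer(dim2))
}
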