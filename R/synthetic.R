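## Synthetic scene and PA-table generator.
##
## Scenes emulate the structure of a dry-season-dominated vegetation-index
## record: irregular within-year observation dates, a seasonal profile whose
## trough (the year's least values) carries the planted piecewise-linear
## trend, cloud/water-masked gaps, and additive index-space noise. Noise is
## applied in index space before the reflectance inversion, so the planted
## slope is the literal ground truth of the quantity the pipeline estimates.

.SIM_BLUE <- 0.05
.SIM_RED <- 0.10
.SIM_OFFSET_GAP <- 0.05   # index gap between trough and off-trough values
.SIM_OFFSET_AMP <- 0.40   # seasonal amplitude per unit of year-fraction
.SIM_TROUGH_CENTER <- 0.35  # dry-season trough as fraction of the year

.rand_sign_slopes <- function(n, sign, magnitude) {
  s <- stats::runif(n, magnitude[1], magnitude[2])
  s * sign
}

.alloc_counts <- function(fractions, n) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fractions * n - counts, decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1L
  }
  counts
}

#' Plant a ground-truth trend structure for one scene
#'
#' Draws per-pixel before/after slopes for the brownest (EVI) and driest
#' (NDII) tracks, plus per-pixel index baselines, and derives the condition
#' categories those slopes imply. With `fractions` given, pixels are
#' allocated to the named categories in those exact proportions (largest
#' remainders receive the rounding surplus) and slopes are drawn with the
#' signs the category requires; otherwise slopes are uniform in
#' `slopeRange`.
#'
#' @param spec A [SceneSpec-class].
#' @param declarationYear Year at which the planted slope switches.
#' @param fractions Optional named proportions over categories of `plant`
#'   mode — e.g. `c(helped = 0.6, harmed = 0.25, unclear = 0.15)` — summing
#'   to 1.
#' @param plant Which classification the fractions target: `"change"`
#'   (helped/harmed/unclear, default) or `"after"`
#'   (improve/decline/unclear).
#' @param slopeRange Uniform slope range (index units/yr) when `fractions`
#'   is `NULL`.
#' @param slopeMagnitude Magnitude range for sign-constrained draws when
#'   `fractions` is given.
#' @param seed Seed; defaults to the scene seed plus one so truth and scene
#'   use distinct streams.
#' @return A [TruthMap-class].
#' @export
simulateTruth <- function(spec, declarationYear,
                          fractions = NULL,
                          plant = c("change", "after"),
                          slopeRange = c(-0.008, 0.008),
                          slopeMagnitude = c(0.002, 0.008),
                          seed = spec@seed + 1L) {
  plant <- match.arg(plant)
  declarationYear <- as.integer(declarationYear)
  if (declarationYear < spec@years[1] || declarationYear > spec@years[2])
    stop("declaration year must lie inside the scene's year range")
  npx <- spec@width * spec@height
  set.seed(as.integer(seed))
  slopes <- matrix(NA_real_, npx, 4L, dimnames = list(NULL, .slope_cols))
  if (is.null(fractions)) {
    for (cc in .slope_cols)
      slopes[, cc] <- stats::runif(npx, slopeRange[1], slopeRange[2])
  } else {
    levelsWanted <- if (plant == "change") c("helped", "harmed", "unclear")
                    else c("improve", "decline", "unclear")
    if (!setequal(names(fractions), levelsWanted) ||
        abs(sum(fractions) - 1) > 1e-8)
      stop("fractions must be named over ", paste(levelsWanted, collapse = "/"),
           " and sum to 1")
    counts <- .alloc_counts(fractions[levelsWanted], npx)
    cat_px <- rep(levelsWanted, counts)
    ## sign pattern per category: (+,+), (-,-), (+,-) resp. for the pair of
    ## quantities the rules inspect
    sgn1 <- ifelse(cat_px == levelsWanted[1], 1,
                   ifelse(cat_px == levelsWanted[2], -1, 1))
    sgn2 <- ifelse(cat_px == levelsWanted[1], 1,
                   ifelse(cat_px == levelsWanted[2], -1, -1))
    if (plant == "after") {
      slopes[, "b_after"] <- .rand_sign_slopes(npx, sgn1, slopeMagnitude)
      slopes[, "d_after"] <- .rand_sign_slopes(npx, sgn2, slopeMagnitude)
      slopes[, "b_before"] <- stats::runif(npx, slopeRange[1], slopeRange[2])
      slopes[, "d_before"] <- stats::runif(npx, slopeRange[1], slopeRange[2])
    } else {
      slopes[, "b_before"] <- stats::runif(npx, -0.002, 0.002)
      slopes[, "d_before"] <- stats::runif(npx, -0.002, 0.002)
      slopes[, "b_after"] <- slopes[, "b_before"] +
        .rand_sign_slopes(npx, sgn1, slopeMagnitude)
      slopes[, "d_after"] <- slopes[, "d_before"] +
        .rand_sign_slopes(npx, sgn2, slopeMagnitude)
    }
  }
  baseEVI <- stats::runif(npx, 0.35, 0.55)
  baseNDII <- stats::runif(npx, 0.20, 0.40)
  new("TruthMap",
    declarationYear = declarationYear, slopes = slopes,
    baseEVI = baseEVI, baseNDII = baseNDII,
    conditionAfter = classifyAfter(slopes[, "b_after"], slopes[, "d_after"]),
    conditionChange = classifyChange(slopes[, "b_before"], slopes[, "b_after"],
                                     slopes[, "d_before"], slopes[, "d_after"]),
    sceneDim = c(spec@height, spec@width))
}

## Piecewise-linear trough line, continuous at the epoch switch.
.trough_line <- function(base, sBefore, sAfter, t, tBreak) {
  if (t < tBreak) base + sBefore * t
  else base + sBefore * tBreak + sAfter * (t - tBreak)
}

## Observation calendar: obsPerYear dates per year, evenly spaced with small
## jitter (a 16-day-revisit approximation), as fractional years since
## 1984-01-01.
.obs_calendar <- function(spec) {
  years <- seq(spec@years[1], spec@years[2])
  m <- spec@obsPerYear
  frac <- lapply(years, function(y) {
    f <- (seq_len(m) - 0.5) / m +
      stats::runif(m, -0.2, 0.2) / m
    sort(pmin(pmax(f, 0), 1 - 1e-9))
  })
  data.frame(
    year = rep(years, each = m),
    frac = unlist(frac)
  )
}

#' Generate a synthetic reflectance stack with known trend structure
#'
#' Builds a dated four-band reflectance stack whose yearly minimum EVI and
#' NDII follow the planted per-pixel piecewise-linear trends of a
#' [TruthMap-class]. Within each year, the `ceiling(0.2 * obsPerYear)`
#' observations nearest the dry-season trough sit exactly on the planted
#' trend line (plus noise); the remaining observations are lifted by a
#' seasonal offset, so the least-20% average recovers the line. Index values
#' are then inverted to reflectances: blue and red are held at plausible
#' constants and NIR (then SWIR1) is solved to hit the target EVI (NDII)
#' exactly. A QA layer marks cloud/water observations drawn at the spec's
#' rates. Fixed `(spec, truth)` reproduce the stack exactly.
#'
#' @param spec A [SceneSpec-class].
#' @param truth A [TruthMap-class], e.g. from [simulateTruth()]; defaults to
#'   random slopes switching halfway through the year range.
#' @return `list(stack = ReflectanceStack, truth = TruthMap)`.
#' @export
simulateStack <- function(spec,
                          truth = simulateTruth(spec,
                            declarationYear = floor(mean(spec@years)))) {
  validObject(spec)
  force(truth)
  npx <- spec@width * spec@height
  set.seed(spec@seed)
  cal <- .obs_calendar(spec)
  nd <- nrow(cal)
  t <- (cal$year - 1984) + cal$frac
  tBreak <- truth@declarationYear - 1984
  ## seasonal offsets shared across pixels; per year the k nearest-to-trough
  ## observations are forced to offset zero
  k <- max(1L, as.integer(ceiling(0.2 * spec@obsPerYear)))
  off <- numeric(nd)
  for (y in unique(cal$year)) {
    sel <- which(cal$year == y)
    d <- abs(cal$frac[sel] - .SIM_TROUGH_CENTER)
    trough <- order(d)[seq_len(min(k, length(sel)))]
    o <- .SIM_OFFSET_GAP + .SIM_OFFSET_AMP * d
    o[trough] <- 0
    off[sel] <- o
  }
  s <- truth@slopes
  eviLine <- vapply(seq_len(nd), function(j)
    .trough_line(truth@baseEVI, s[, "b_before"], s[, "b_after"], t[j], tBreak),
    numeric(npx))
  ndiiLine <- vapply(seq_len(nd), function(j)
    .trough_line(truth@baseNDII, s[, "d_before"], s[, "d_after"], t[j], tBreak),
    numeric(npx))
  evi <- sweep(eviLine, 2L, off, "+")
  ndii <- sweep(ndiiLine, 2L, 0.5 * off, "+")
  if (spec@noiseSD > 0) {
    evi <- evi + matrix(stats::rnorm(npx * nd, 0, spec@noiseSD), npx, nd)
    ndii <- ndii + matrix(stats::rnorm(npx * nd, 0, spec@noiseSD), npx, nd)
  }
  ## invert to reflectances: one degree of freedom per index
  nir <- (0.25 + 1.225 * evi) / (2.5 - evi)
  swir1 <- nir * (1 - ndii) / (1 + ndii)
  nClip <- sum(nir < 1e-4 | nir > 1 | swir1 < 1e-4 | swir1 > 1)
  if (nClip > 0) {
    warning(sprintf(
      "simulateStack: %d observations clipped to the [0,1] reflectance range",
      nClip))
    nir <- pmin(pmax(nir, 1e-4), 1)
    swir1 <- pmin(pmax(swir1, 1e-4), 1)
  }
  qa <- matrix(sample.int(3L, npx * nd, replace = TRUE,
    prob = c(1 - spec@cloudFraction - spec@waterFraction,
             spec@cloudFraction, spec@waterFraction)) - 1L, npx, nd)
  stack <- reflectanceStack(
    blue = matrix(.SIM_BLUE, npx, nd), red = matrix(.SIM_RED, npx, nd),
    nir = nir, swir1 = swir1, qa = qa,
    timestamp = t, year = cal$year, scene = spec
  )
  list(stack = stack, truth = truth)
}

#' Generate a synthetic protected-area attribute table
#'
#' Lays out rectangular TRs (impacts) and WLSs (controls) in
#' 300 km x 300 km state blocks on a projected plane, with areas, long-term
#' mean annual rainfall and (for TRs) declaration years drawn from the
#' configured ranges. PAs are assigned to states round-robin; whenever
#' `nWLS >= nStates`, the first WLS of each state is forced to meet the
#' 75 km2 matching floor so every state has at least one eligible control.
#' Deterministic for a fixed seed.
#'
#' @param nStates Number of states (>= 1).
#' @param nTR,nWLS Counts of TRs and WLSs (>= 0).
#' @param seed Integer seed.
#' @param rainfallRange,declarationRange,areaRangeTR,areaRangeWLS Draw
#'   ranges: rainfall mm/yr, TR declaration years, areas km2.
#' @return A [PATable] `data.frame`; the draw ranges are attached as
#'   attributes.
#' @export
generatePATable <- function(nStates, nTR, nWLS, seed,
                            rainfallRange = c(800, 3000),
                            declarationRange = c(1989L, 2007L),
                            areaRangeTR = c(200, 2000),
                            areaRangeWLS = c(30, 1500)) {
  if (nStates < 1L) stop("nStates must be >= 1")
  if (nTR < 0L || nWLS < 0L) stop("nTR and nWLS must be >= 0")
  set.seed(as.integer(seed))
  block <- 300e3  # metres
  stateOf <- function(i) sprintf("S%02d", (i - 1L) %% nStates + 1L)
  mk <- function(n, status, areaRange) {
    if (n == 0L) return(NULL)
    idx <- seq_len(n)
    state <- stateOf(idx)
    stateNum <- (idx - 1L) %% nStates
    area <- stats::runif(n, areaRange[1], areaRange[2])
    if (status == "WLS" && nWLS >= nStates) {
      first <- !duplicated(state)
      area[first] <- pmax(area[first], stats::runif(sum(first), 75, areaRange[2]))
    }
    aspect <- stats::runif(n, 0.5, 2)
    w <- sqrt(area * 1e6 * aspect)
    h <- area * 1e6 / w
    x0 <- stateNum * block + stats::runif(n, 0, pmax(block - w, 1))
    y0 <- stats::runif(n, 0, pmax(block - h, 1))
    data.frame(
      id = sprintf("%s%02d", status, idx),
      name = sprintf("%s %02d", status, idx),
      status = status, state = state,
      area_km2 = area,
      rainfall_mm = stats::runif(n, rainfallRange[1], rainfallRange[2]),
      declaration_year = if (status == "TR")
        sample(seq(declarationRange[1], declarationRange[2]), n, replace = TRUE)
      else NA_integer_,
      xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(mk(nTR, "TR", areaRangeTR), mk(nWLS, "WLS", areaRangeWLS))
  if (is.null(out))
    out <- data.frame(
      id = character(), name = character(), status = character(),
      state = character(), area_km2 = numeric(), rainfall_mm = numeric(),
      declaration_year = integer(), xmin = numeric(), ymin = numeric(),
      xmax = numeric(), ymax = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rainfallRange") <- rainfallRange
  attr(out, "declarationRange") <- declarationRange
  out
}
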