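#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames colData rowData
NULL

## Pixels are stored row-major (row 1, col 1..w; row 2, ...) as the rows of a
## SummarizedExperiment; observation dates (or composite years) are its columns.

#' Scene specification for the synthetic reflectance generator
#'
#' A `SceneSpec` describes the grid, the observation calendar and the noise
#' regime of one synthetic scene: a rectangular pixel grid observed several
#' times per year over an inclusive span of calendar years, with a fraction of
#' observations lost to cloud or water masking and additive Gaussian noise on
#' the vegetation-index values.
#'
#' @slot width,height Grid size in pixels.
#' @slot pixelSize Pixel edge length in metres (default 30, the Landsat TM
#'   ground sample distance).
#' @slot origin Projected coordinates (metres) of the lower-left scene corner.
#' @slot years Inclusive calendar-year range `c(first, last)`; must span at
#'   least two years.
#' @slot obsPerYear Number of observation dates per calendar year.
#' @slot cloudFraction,waterFraction Per-observation masking probabilities.
#' @slot noiseSD Standard deviation of additive index-space noise
#'   (dimensionless index units).
#' @slot seed Integer seed; all randomness of the generator flows from it.
#' @seealso [sceneSpec()], [simulateStack()]
#' @export
setClass("SceneSpec",
  representation(
    width = "integer", height = "integer",
    pixelSize = "numeric", origin = "numeric",
    years = "integer", obsPerYear = "integer",
    cloudFraction = "numeric", waterFraction = "numeric",
    noiseSD = "numeric", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be >= 1")
  if (length(object@years) != 2L || diff(object@years) < 1L)
    msg <- c(msg, "years must be an inclusive range spanning >= 2 years")
  if (object@obsPerYear < 1L)
    msg <- c(msg, "obsPerYear must be >= 1")
  p <- c(object@cloudFraction, object@waterFraction)
  if (any(p < 0) || any(p > 1) || sum(p) > 1)
    msg <- c(msg, "cloudFraction and waterFraction must lie in [0,1] with sum <= 1")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' @param width,height Grid size in pixels.
#' @param pixelSize Pixel size in metres.
#' @param origin Projected coordinates of the lower-left corner, metres.
#' @param years Inclusive calendar-year range, e.g. `c(1984, 2012)`.
#' @param obsPerYear Observations per calendar year (23 approximates the
#'   16-day Landsat revisit).
#' @param cloudFraction,waterFraction Masking probabilities in `[0, 1]`.
#' @param noiseSD Additive index-space noise standard deviation.
#' @param seed Integer seed for the generator.
#' @return A validated [SceneSpec-class] object.
#' @examples
#' sceneSpec(width = 8, height = 8, years = c(1984, 2012), seed = 1)
#' @export
sceneSpec <- function(width, height, pixelSize = 30, origin = c(0, 0),
                      years = c(1984L, 2012L), obsPerYear = 23L,
                      cloudFraction = 0, waterFraction = 0,
                      noiseSD = 0, seed = 1L) {
  new("SceneSpec",
    width = as.integer(width), height = as.integer(height),
    pixelSize = as.numeric(pixelSize), origin = as.numeric(origin),
    years = as.integer(years), obsPerYear = as.integer(obsPerYear),
    cloudFraction = as.numeric(cloudFraction),
    waterFraction = as.numeric(waterFraction),
    noiseSD = as.numeric(noiseSD), seed = as.integer(seed)
  )
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px @ %g m, %d-%d (%d obs/yr), cloud %.2f water %.2f, noise sd %.3f, seed %d\n",
    object@width, object@height, object@pixelSize,
    object@years[1], object@years[2], object@obsPerYear,
    object@cloudFraction, object@waterFraction, object@noiseSD, object@seed
  ))
})

#' Dated multiband reflectance stack
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass holding one scene's surface-reflectance time series. Rows are
#' pixels (row-major over the grid, with grid coordinates in `rowData`);
#' columns are observation dates with fractional-year timestamps in
#' `colData`. Assays are the four reflectance bands `blue`, `red`, `nir`,
#' `swir1` (floats in `[0, 1]`) and a `qa` layer coding each observation as
#' clear (0), cloud (1) or water (2).
#'
#' @seealso [reflectanceStack()], [applyQAMask()], [computeIndices()]
#' @export
setClass("ReflectanceStack", contains = "SummarizedExperiment")

.stack_bands <- c("blue", "red", "nir", "swir1")

setValidity("ReflectanceStack", function(object) {
  msg <- character()
  need <- c(.stack_bands, "qa")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  if (!all(c("timestamp", "year") %in% colnames(colData(object))))
    msg <- c(msg, "colData must include timestamp and year")
  if ("qa" %in% assayNames(object)) {
    qa <- assay(object, "qa")
    if (!all(qa %in% c(0L, 1L, 2L)))
      msg <- c(msg, "qa values must be 0 (clear), 1 (cloud) or 2 (water)")
  }
  if ("timestamp" %in% colnames(colData(object)) &&
      any(colData(object)$timestamp < 0))
    msg <- c(msg, "timestamps must be >= 0 (fractional years since 1984-01-01)")
  if (length(msg)) msg else TRUE
})

#' Assemble a ReflectanceStack from band matrices
#'
#' @param blue,red,nir,swir1 Numeric pixel-by-date matrices of reflectance in
#'   `[0, 1]`.
#' @param qa Integer pixel-by-date matrix: 0 clear, 1 cloud, 2 water.
#' @param timestamp Fractional years since 1984-01-01, one per date column.
#' @param year Calendar year of each date column.
#' @param scene Optional [SceneSpec-class] stored in `metadata()`.
#' @return A [ReflectanceStack-class].
#' @export
reflectanceStack <- function(blue, red, nir, swir1, qa, timestamp, year,
                             scene = NULL) {
  npx <- nrow(blue)
  rd <- if (!is.null(scene)) {
    DataFrame(
      row = rep(seq_len(scene@height), each = scene@width),
      col = rep(seq_len(scene@width), times = scene@height)
    )
  } else DataFrame(row = seq_len(npx), col = rep(1L, npx))
  se <- SummarizedExperiment(
    assays = list(blue = blue, red = red, nir = nir, swir1 = swir1,
                  qa = qa),
    rowData = rd,
    colData = DataFrame(timestamp = as.numeric(timestamp),
                        year = as.integer(year))
  )
  md <- list()
  if (!is.null(scene)) md$scene <- scene
  out <- new("ReflectanceStack", se)
  metadata(out) <- md
  out
}

#' Per-date vegetation-index stack
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass with assays `evi` (brownest track) and `ndii` (driest track) on
#' the pixel-by-date layout of the [ReflectanceStack-class] it was computed
#' from. Invalid observations (masked, singular denominator, out-of-range
#' index) are `NA`.
#'
#' @seealso [computeIndices()], [buildComposites()]
#' @export
setClass("IndexStack", contains = "SummarizedExperiment")

setValidity("IndexStack", function(object) {
  msg <- character()
  if (!all(c("evi", "ndii") %in% assayNames(object)))
    msg <- c(msg, "assays must include evi and ndii")
  if (!all(c("timestamp", "year") %in% colnames(colData(object))))
    msg <- c(msg, "colData must include timestamp and year")
  if (length(msg)) msg else TRUE
})

#' Annual brownest/driest composite series
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass with one column per calendar year. For each of the two tracks
#' (brownest = EVI, driest = NDII) it stores the robust annual minimum value,
#' its fractional-year date-stamp and the number of valid observations that
#' year: assays `evi`, `eviTime`, `eviN`, `ndii`, `ndiiTime`, `ndiiN`.
#' Absent composites (no valid observation in the year) are `NA` with count 0.
#'
#' @seealso [buildComposites()], [estimateEpochSlopes()]
#' @export
setClass("AnnualCompositeSeries", contains = "SummarizedExperiment")

setValidity("AnnualCompositeSeries", function(object) {
  msg <- character()
  need <- c("evi", "eviTime", "eviN", "ndii", "ndiiTime", "ndiiN")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  if (!"year" %in% colnames(colData(object)))
    msg <- c(msg, "colData must include year")
  else if (is.unsorted(colData(object)$year, strictly = TRUE))
    msg <- c(msg, "years must be strictly increasing")
  if (length(msg)) msg else TRUE
})

.slope_cols <- c("b_before", "b_after", "d_before", "d_after")

#' Per-pixel epoch-wise slope maps
#'
#' Holds the four per-pixel trend estimates of the BACI design: Sen's slope of
#' the annual brownest (EVI, `b`) and driest (NDII, `d`) composites in the
#' epochs before and after declaration, in index units per year. A slope is
#' valid only where its epoch had at least `minPoints` valid composite years.
#'
#' @slot slopes Numeric pixel-by-4 matrix, columns `b_before`, `b_after`,
#'   `d_before`, `d_after`; `NA` where invalid.
#' @slot nYears Integer matrix of valid composite-year counts, same layout.
#' @slot epochs List with inclusive year ranges `before` and `after` (either
#'   may be `NULL` in after-only mode).
#' @slot declarationYear Declaration year splitting the epochs.
#' @slot minPoints Minimum valid years per epoch for a pixel to keep a slope.
#' @slot sceneDim `c(height, width)` of the pixel grid.
#' @seealso [estimateEpochSlopes()], [slopeMatrix()], [slopeValid()]
#' @export
setClass("SlopeMaps",
  representation(
    slopes = "matrix", nYears = "matrix", epochs = "list",
    declarationYear = "integer", minPoints = "integer",
    sceneDim = "integer"
  )
)

setValidity("SlopeMaps", function(object) {
  msg <- character()
  if (!identical(colnames(object@slopes), .slope_cols))
    msg <- c(msg, "slopes columns must be b_before, b_after, d_before, d_after")
  if (!identical(dim(object@slopes), dim(object@nYears)))
    msg <- c(msg, "slopes and nYears must share dimensions")
  bad <- !is.na(object@slopes) & object@nYears < object@minPoints
  if (any(bad))
    msg <- c(msg, "a slope is present for a pixel-epoch with too few valid years")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SlopeMaps", function(object) {
  cat(sprintf("SlopeMaps: %d pixels (%d x %d grid), declaration %d\n",
    nrow(object@slopes), object@sceneDim[1], object@sceneDim[2],
    object@declarationYear))
  for (ep in names(object@epochs)) {
    r <- object@epochs[[ep]]
    if (!is.null(r)) cat(sprintf("  %s epoch: %d-%d\n", ep, r[1], r[2]))
  }
  vfrac <- colMeans(!is.na(object@slopes))
  cat("  valid fraction:",
      paste(sprintf("%s %.2f", .slope_cols, vfrac), collapse = ", "), "\n")
})

#' Ground-truth map for synthetic scenes
#'
#' Stores the per-pixel trend structure a synthetic scene was built from: the
#' true before/after slopes for both tracks, the index baselines, and the
#' condition categories those slopes imply under the classification rules.
#' The categories are derived in the constructor from the same rules the
#' pipeline applies, so recovery tests compare like with like.
#'
#' @slot declarationYear Year at which the planted slope switches.
#' @slot slopes True slopes, pixel-by-4 matrix, columns as in
#'   [SlopeMaps-class].
#' @slot baseEVI,baseNDII Per-pixel index values at the start of the series.
#' @slot conditionAfter Factor of true after-epoch categories
#'   (improve/decline/unclear).
#' @slot conditionChange Factor of true change categories
#'   (helped/harmed/unclear).
#' @slot sceneDim `c(height, width)` of the grid.
#' @seealso [simulateTruth()], [simulateStack()]
#' @export
setClass("TruthMap",
  representation(
    declarationYear = "integer", slopes = "matrix",
    baseEVI = "numeric", baseNDII = "numeric",
    conditionAfter = "factor", conditionChange = "factor",
    sceneDim = "integer"
  )
)

setValidity("TruthMap", function(object) {
  msg <- character()
  if (!identical(colnames(object@slopes), .slope_cols))
    msg <- c(msg, "slopes columns must be b_before, b_after, d_before, d_after")
  s <- object@slopes
  expAfter <- classifyAfter(s[, "b_after"], s[, "d_after"])
  expChange <- classifyChange(s[, "b_before"], s[, "b_after"],
                              s[, "d_before"], s[, "d_after"])
  if (!identical(as.character(expAfter), as.character(object@conditionAfter)))
    msg <- c(msg, "conditionAfter inconsistent with true slopes")
  if (!identical(as.character(expChange), as.character(object@conditionChange)))
    msg <- c(msg, "conditionChange inconsistent with true slopes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthMap", function(object) {
  cat(sprintf("TruthMap: %d pixels (%d x %d), declaration %d\n",
    nrow(object@slopes), object@sceneDim[1], object@sceneDim[2],
    object@declarationYear))
  cat("  after:", paste(sprintf("%s %.2f",
    levels(object@conditionAfter),
    as.numeric(table(object@conditionAfter)) / length(object@conditionAfter)),
    collapse = ", "), "\n")
  cat("  change:", paste(sprintf("%s %.2f",
    levels(object@conditionChange),
    as.numeric(table(object@conditionChange)) / length(object@conditionChange)),
    collapse = ", "), "\n")
})

#' Analysis thresholds and options
#'
#' One object housing every tunable of the pipeline, pre-filled with the
#' study defaults: a 500 mm rainfall matching window, a 75 km2 control-area
#' floor, at least 5 valid composite years per pixel per epoch, at most 20%
#' of a PA's area with insufficient data, the least-20% robust annual
#' minimum, and a 15 percentage-point substantiality threshold for matched
#' pair differences.
#'
#' @slot rainfallWindow Maximum |rainfall difference| for a match, mm/yr.
#' @slot wlsMinArea Minimum control (WLS) area, km2.
#' @slot minPointsPerEpoch Minimum valid composite years per pixel per epoch.
#' @slot maxInsufficientFraction Maximum insufficient-area fraction for a PA
#'   to be retained in an epoch.
#' @slot robustMinFraction Fraction of a year's lowest values averaged into
#'   the composite.
#' @slot substantialThreshold Percentage-point difference in improvement or
#'   decline area deemed substantial.
#' @slot declarationEpoch Which epoch owns the declaration year
#'   (`"after"` default).
#' @slot distanceMetric `"boundary"` (minimum separation, default) or
#'   `"centroid"`.
#' @slot estimator `"theil-sen"` (median of pairwise slopes, default) or
#'   `"siegel"` (repeated medians).
#' @slot timestampMode `"subset-mean"` (date-stamp of the averaged minimum,
#'   default) or `"argmin"`.
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    rainfallWindow = "numeric", wlsMinArea = "numeric",
    minPointsPerEpoch = "integer", maxInsufficientFraction = "numeric",
    robustMinFraction = "numeric", substantialThreshold = "numeric",
    declarationEpoch = "character", distanceMetric = "character",
    estimator = "character", timestampMode = "character"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@rainfallWindow <= 0) msg <- c(msg, "rainfallWindow must be > 0")
  if (object@wlsMinArea <= 0) msg <- c(msg, "wlsMinArea must be > 0")
  if (object@minPointsPerEpoch < 1L)
    msg <- c(msg, "minPointsPerEpoch must be >= 1")
  if (object@maxInsufficientFraction <= 0 || object@maxInsufficientFraction > 1)
    msg <- c(msg, "maxInsufficientFraction must be in (0, 1]")
  if (object@robustMinFraction <= 0 || object@robustMinFraction > 1)
    msg <- c(msg, "robustMinFraction must be in (0, 1]")
  if (object@substantialThreshold <= 0)
    msg <- c(msg, "substantialThreshold must be > 0")
  if (!object@declarationEpoch %in% c("after", "before"))
    msg <- c(msg, "declarationEpoch must be 'after' or 'before'")
  if (!object@distanceMetric %in% c("boundary", "centroid"))
    msg <- c(msg, "distanceMetric must be 'boundary' or 'centroid'")
  if (!object@estimator %in% c("theil-sen", "siegel"))
    msg <- c(msg, "estimator must be 'theil-sen' or 'siegel'")
  if (!object@timestampMode %in% c("subset-mean", "argmin"))
    msg <- c(msg, "timestampMode must be 'subset-mean' or 'argmin'")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param rainfallWindow,wlsMinArea,minPointsPerEpoch,maxInsufficientFraction,robustMinFraction,substantialThreshold
#'   Thresholds; see [AnalysisConfig-class] for meaning and defaults.
#' @param declarationEpoch,distanceMetric,estimator,timestampMode Options; see
#'   [AnalysisConfig-class].
#' @return A validated [AnalysisConfig-class].
#' @examples
#' analysisConfig()  # study defaults
#' @export
analysisConfig <- function(rainfallWindow = 500, wlsMinArea = 75,
                           minPointsPerEpoch = 5L,
                           maxInsufficientFraction = 0.20,
                           robustMinFraction = 0.20,
                           substantialThreshold = 15,
                           declarationEpoch = c("after", "before"),
                           distanceMetric = c("boundary", "centroid"),
                           estimator = c("theil-sen", "siegel"),
                           timestampMode = c("subset-mean", "argmin")) {
  new("AnalysisConfig",
    rainfallWindow = as.numeric(rainfallWindow),
    wlsMinArea = as.numeric(wlsMinArea),
    minPointsPerEpoch = as.integer(minPointsPerEpoch),
    maxInsufficientFraction = as.numeric(maxInsufficientFraction),
    robustMinFraction = as.numeric(robustMinFraction),
    substantialThreshold = as.numeric(substantialThreshold),
    declarationEpoch = match.arg(declarationEpoch),
    distanceMetric = match.arg(distanceMetric),
    estimator = match.arg(estimator),
    timestampMode = match.arg(timestampMode)
  )
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  cat(sprintf("  rainfall window %g mm, WLS area floor %g km2\n",
    object@rainfallWindow, object@wlsMinArea))
  cat(sprintf("  >= %d points/pixel/epoch, <= %.0f%% insufficient PA area\n",
    object@minPointsPerEpoch, 100 * object@maxInsufficientFraction))
  cat(sprintf("  robust minimum: least %.0f%%; substantial: >= %g points\n",
    100 * object@robustMinFraction, object@substantialThreshold))
  cat(sprintf("  declaration year in '%s' epoch; %s distance; %s estimator\n",
    object@declarationEpoch, object@distanceMetric, object@estimator))
})
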