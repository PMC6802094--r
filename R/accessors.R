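#' Accessors for stack and composite objects
#'
#' Small helpers for reaching into the SummarizedExperiment-based containers
#' without touching assay slots directly.
#'
#' @param x A [ReflectanceStack-class], [IndexStack-class] or
#'   [AnnualCompositeSeries-class].
#' @param band For `bandValues()`, one of `"blue"`, `"red"`, `"nir"`,
#'   `"swir1"`, `"qa"` (stacks) or `"evi"`, `"ndii"` (index stacks).
#' @return `bandValues()` a pixel-by-date matrix; `obsTime()` the fractional
#'   year of each column; `obsYear()` its calendar year; `compositeYears()`
#'   the composite series' calendar years.
#' @name stack-accessors
NULL

#' @rdname stack-accessors
#' @export
bandValues <- function(x, band) assay(x, band)

#' @rdname stack-accessors
#' @export
obsTime <- function(x) colData(x)$timestamp

#' @rdname stack-accessors
#' @export
obsYear <- function(x) colData(x)$year

#' @rdname stack-accessors
#' @export
compositeYears <- function(x) colData(x)$year

#' Accessors for SlopeMaps
#'
#' @param x A [SlopeMaps-class].
#' @return `slopeMatrix()` the pixel-by-4 slope matrix (`NA` where invalid);
#'   `slopeValid()` the matching logical validity matrix; `slopeEpochs()` the
#'   list of inclusive epoch year ranges.
#' @name slope-accessors
NULL

#' @rdname slope-accessors
#' @export
slopeMatrix <- function(x) x@slopes

#' @rdname slope-accessors
#' @export
slopeValid <- function(x) {
  v <- x@nYears >= x@minPoints
  dimnames(v) <- dimnames(x@slopes)
  v
}

#' @rdname slope-accessors
#' @export
slopeEpochs <- function(x) x@epochs

#' Accessors for TruthMap
#'
#' @param x A [TruthMap-class].
#' @return `trueSlopes()` the planted pixel-by-4 slope matrix;
#'   `trueCondition()` the implied category factor for the requested mode.
#' @param mode `"after"` (improve/decline/unclear) or `"change"`
#'   (helped/harmed/unclear).
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
trueSlopes <- function(x) x@slopes

#' @rdname truth-accessors
#' @export
trueCondition <- function(x, mode = c("after", "change")) {
  mode <- match.arg(mode)
  if (mode == "after") x@conditionAfter else x@conditionChange
}
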