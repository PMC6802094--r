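## Annual brownest/driest composites: the yearly minimum replaced by the
## average of the year's least 20% of valid values, date-stamped accordingly.

#' Robust annual minimum of one year's index observations
#'
#' Takes the `k = ceiling(f * n_valid)` smallest valid values of a year
#' (`f` = 0.20 by default, and always at least one observation) and returns
#' their mean together with a date-stamp. With `timestampMode =
#' "subset-mean"` the stamp is the mean fractional-year timestamp of the
#' selected observations; with `"argmin"` it is the timestamp of the single
#' smallest value. Ties at the k-th smallest value are broken by earliest
#' timestamp, so the result is deterministic.
#'
#' @param values Numeric index values of one pixel, one track, one calendar
#'   year; `NA` marks invalid observations.
#' @param timestamps Fractional years since 1984-01-01, parallel to `values`.
#' @param fraction Fraction of lowest values to average (default 0.20).
#' @param timestampMode `"subset-mean"` (default) or `"argmin"`.
#' @return `list(value, timestamp, n)` where `n` is the count of valid
#'   observations, or `list(value = NA, timestamp = NA, n = 0)` when the year
#'   has no valid observation (absent composite).
#' @examples
#' robustAnnualMinimum(c(0.1, 0.2, 0.3, 0.4, 0.5), 0:4 / 23)  # k = 1
#' robustAnnualMinimum(seq(0.1, 1, by = 0.1), 0:9 / 23)       # k = 2
#' @export
robustAnnualMinimum <- function(values, timestamps, fraction = 0.20,
                                timestampMode = c("subset-mean", "argmin")) {
  timestampMode <- match.arg(timestampMode)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L)
    return(list(value = NA_real_, timestamp = NA_real_, n = 0L))
  v <- values[ok]
  t <- timestamps[ok]
  k <- max(1L, as.integer(ceiling(fraction * n)))
  o <- order(v, t)
  sel <- o[seq_len(k)]
  ts <- if (timestampMode == "subset-mean") mean(t[sel]) else t[o[1L]]
  list(value = mean(v[sel]), timestamp = ts, n = n)
}

## Row-wise robust minimum over a pixel-by-observation matrix (one year).
.robust_min_matrix <- function(m, ts, fraction, timestampMode) {
  res <- t(apply(m, 1L, function(v) {
    r <- robustAnnualMinimum(v, ts, fraction, timestampMode)
    c(r$value, r$timestamp, r$n)
  }))
  colnames(res) <- c("value", "timestamp", "n")
  res
}

#' Build annual brownest and driest composite series
#'
#' For every pixel, calendar year and track, applies [robustAnnualMinimum()]
#' to the year's valid index observations, recording the composite value, its
#' fractional-year date-stamp and the valid-observation count. Years with no
#' valid observation get an absent (`NA`) composite.
#'
#' @param indexStack An [IndexStack-class] from [computeIndices()].
#' @param years Calendar years to composite; default all years present.
#' @param fraction Fraction of lowest values averaged per year (default 0.20).
#' @param timestampMode Passed to [robustAnnualMinimum()].
#' @return An [AnnualCompositeSeries-class] with one column per year.
#' @export
buildComposites <- function(indexStack, years = NULL, fraction = 0.20,
                            timestampMode = c("subset-mean", "argmin")) {
  timestampMode <- match.arg(timestampMode)
  obsYears <- obsYear(indexStack)
  if (is.null(years)) years <- sort(unique(obsYears))
  years <- as.integer(years)
  if (length(years) == 0L) stop("empty year range")
  if (!all(years %in% obsYears))
    stop("index stack does not cover all requested years")
  npx <- nrow(indexStack)
  ny <- length(years)
  tmpl <- matrix(NA_real_, npx, ny)
  out <- list(evi = tmpl, eviTime = tmpl, eviN = tmpl,
              ndii = tmpl, ndiiTime = tmpl, ndiiN = tmpl)
  ts <- obsTime(indexStack)
  evi <- assay(indexStack, "evi")
  ndii <- assay(indexStack, "ndii")
  for (j in seq_along(years)) {
    sel <- which(obsYears == years[j])
    re <- .robust_min_matrix(evi[, sel, drop = FALSE], ts[sel],
                             fraction, timestampMode)
    rn <- .robust_min_matrix(ndii[, sel, drop = FALSE], ts[sel],
                             fraction, timestampMode)
    out$evi[, j] <- re[, "value"]; out$eviTime[, j] <- re[, "timestamp"]
    out$eviN[, j] <- re[, "n"]
    out$ndii[, j] <- rn[, "value"]; out$ndiiTime[, j] <- rn[, "timestamp"]
    out$ndiiN[, j] <- rn[, "n"]
  }
  se <- SummarizedExperiment(
    assays = out,
    rowData = rowData(indexStack),
    colData = DataFrame(year = years)
  )
  res <- new("AnnualCompositeSeries", se)
  metadata(res) <- metadata(indexStack)
  res
}
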