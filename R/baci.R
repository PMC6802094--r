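## Condition classification from slope signs, PA composition summaries and
## matched-pair comparison.

.after_levels <- c("improve", "decline", "unclear", "insufficient")
.change_levels <- c("helped", "harmed", "unclear", "insufficient")

.sign_pair_category <- function(a, b, pos, neg, levels) {
  out <- rep("unclear", length(a))
  out[a > 0 & b > 0] <- pos
  out[a < 0 & b < 0] <- neg
  out[is.na(a) | is.na(b)] <- "insufficient"
  factor(out, levels = levels)
}

#' Classify after-epoch vegetation condition
#'
#' Per-pixel condition from the signs of the after-epoch slopes of the
#' brownest (EVI) and driest (NDII) composites: both positive is `improve`,
#' both negative `decline`, opposite signs `unclear`. A zero slope — possible
#' through ties in the pairwise-slope median — falls to `unclear`, since the
#' rules use strict inequalities. A missing slope yields `insufficient`.
#'
#' @param sbAfter,sdAfter After-epoch slopes for the brownest and driest
#'   tracks (vectors; `NA` = insufficient data).
#' @return Factor with levels improve, decline, unclear, insufficient.
#' @examples
#' classifyAfter(c(0.004, -0.003, 0.004), c(0.002, -0.001, -0.001))
#' @export
classifyAfter <- function(sbAfter, sdAfter) {
  .sign_pair_category(sbAfter, sdAfter, "improve", "decline", .after_levels)
}

#' Classify before-to-after condition change
#'
#' Per-pixel response to declaration from the signs of the slope differences
#' (after minus before) in both tracks: both positive is `helped`, both
#' negative `harmed`, opposite signs `unclear` (zero differences fall to
#' `unclear`; any missing slope yields `insufficient`).
#'
#' @param sbBefore,sbAfter,sdBefore,sdAfter Epoch slopes for the brownest
#'   (`sb*`) and driest (`sd*`) tracks.
#' @return Factor with levels helped, harmed, unclear, insufficient.
#' @examples
#' classifyChange(0.001, 0.003, 0.001, 0.002)  # helped
#' @export
classifyChange <- function(sbBefore, sbAfter, sdBefore, sdAfter) {
  .sign_pair_category(sbAfter - sbBefore, sdAfter - sdBefore,
                      "helped", "harmed", .change_levels)
}

#' Classify every pixel of a SlopeMaps
#'
#' @param slopeMaps A [SlopeMaps-class].
#' @param mode `"after"` (condition in the after epoch, Eq.-1-style rules) or
#'   `"change"` (before-to-after response).
#' @return A per-pixel category factor.
#' @export
classifyPixels <- function(slopeMaps, mode = c("after", "change")) {
  mode <- match.arg(mode)
  s <- slopeMatrix(slopeMaps)
  if (mode == "after")
    classifyAfter(s[, "b_after"], s[, "d_after"])
  else
    classifyChange(s[, "b_before"], s[, "b_after"],
                   s[, "d_before"], s[, "d_after"])
}

#' PA-level condition composition
#'
#' Percentage of a protected area's pixels in each condition (or
#' condition-change) category, including the insufficient-data pixels as a
#' fourth reported category so that the percentages always total 100.
#'
#' @param categories Per-pixel category factor from [classifyPixels()].
#' @param paMask Logical PA membership over the pixels (default: all).
#' @param paId Identifier copied into the output.
#' @param sufficient Result of [paSufficiency()] for the epochs involved; a
#'   dropped PA is refused with an error rather than summarized.
#' @return One-row `data.frame`: `pa_id`, `mode`, one percentage column per
#'   category, and `n_pixels`.
#' @export
composition <- function(categories, paMask = NULL, paId = "PA",
                        sufficient = TRUE) {
  if (!isTRUE(sufficient))
    stop(sprintf("PA %s was dropped by the area-sufficiency rule", paId))
  if (is.null(paMask)) paMask <- rep(TRUE, length(categories))
  if (!any(paMask)) stop("empty PA mask")
  cats <- categories[paMask]
  pct <- 100 * as.numeric(table(cats)) / length(cats)
  names(pct) <- levels(cats)
  mode <- if ("improve" %in% levels(cats)) "after" else "change"
  out <- data.frame(pa_id = paId, mode = mode, t(pct),
                    n_pixels = length(cats),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.pos_neg_cols <- function(mode) {
  if (mode == "after") c("improve", "decline") else c("helped", "harmed")
}

#' Compare a matched impact-control pair of compositions
#'
#' The impact PA (TR) is `better` than its control (WLS) when it
#' simultaneously has a greater percentage of area improving (helped) and a
#' lesser percentage declining (harmed); `worse` when both are reversed; any
#' other combination is `ambiguous`. The difference is `substantial` when the
#' improvement or the decline percentages differ by at least
#' `substantialThreshold` points (default 15).
#'
#' @param tr,wls One-row compositions from [composition()], same mode.
#' @param config An [AnalysisConfig-class] (for the substantiality
#'   threshold).
#' @return One-row `data.frame`: `tr_id`, `wls_id`, `mode`, `verdict`
#'   (better/worse/ambiguous), `substantial`, and the two signed differences.
#' @export
comparePair <- function(tr, wls, config = analysisConfig()) {
  if (!identical(tr$mode, wls$mode))
    stop("compositions have different epoch modes")
  cols <- .pos_neg_cols(tr$mode)
  dPos <- tr[[cols[1]]] - wls[[cols[1]]]
  dNeg <- tr[[cols[2]]] - wls[[cols[2]]]
  verdict <- if (dPos > 0 && dNeg < 0) "better"
             else if (dPos < 0 && dNeg > 0) "worse"
             else "ambiguous"
  substantial <- abs(dPos) >= config@substantialThreshold ||
                 abs(dNeg) >= config@substantialThreshold
  data.frame(
    tr_id = tr$pa_id, wls_id = wls$pa_id, mode = tr$mode,
    verdict = verdict, substantial = substantial,
    d_positive = dPos, d_negative = dNeg,
    stringsAsFactors = FALSE
  )
}

#' Export compositions to the 3-category ternary simplex
#'
#' Renormalizes each PA's composition over the three analysed categories
#' (dropping the insufficient share) so the rows live on the ternary simplex
#' used to plot condition compositions.
#'
#' @param summaries A `data.frame` of row-bound [composition()] outputs
#'   sharing one mode (may be empty).
#' @return `data.frame` with `pa_id` and the three category proportions
#'   summing to 1 per row (empty if `summaries` is empty).
#' @export
ternaryExport <- function(summaries) {
  if (NROW(summaries) == 0L)
    return(data.frame(pa_id = character(), positive = numeric(),
                      negative = numeric(), unclear = numeric()))
  cols <- c(.pos_neg_cols(summaries$mode[1]), "unclear")
  m <- as.matrix(summaries[, cols])
  m <- m / rowSums(m)
  out <- data.frame(pa_id = summaries$pa_id, m, stringsAsFactors = FALSE)
  names(out) <- c("pa_id", cols)
  rownames(out) <- NULL
  out
}
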