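## Vegetation indices. EVI uses the standard soil/aerosol-adjusted
## parameterization (G = 2.5, C1 = 6, C2 = 7.5, L = 1); NDII is the
## normalized difference of NIR and the 1.55-1.75 um shortwave infrared.

.EVI_G <- 2.5
.EVI_C1 <- 6
.EVI_C2 <- 7.5
.EVI_L <- 1

## EVI from surface-reflectance artifacts can be unbounded; values outside
## this range are treated as invalid so they cannot contaminate the robust
## annual minimum.
.EVI_RANGE <- c(-1, 2)

#' Enhanced vegetation index
#'
#' EVI = G (NIR - Red) / (NIR + C1 Red - C2 Blue + L) with the standard
#' coefficients G = 2.5, C1 = 6, C2 = 7.5, L = 1. Vectorized; `NA` inputs
#' (masked observations) and near-zero denominators yield `NA`. Values
#' outside `[-1, 2]` — reflectance artifacts, not vegetation — are also
#' returned as `NA`.
#'
#' @param blue,red,nir Surface reflectances in `[0, 1]` (scalars, vectors or
#'   matrices of equal shape).
#' @return The EVI, same shape as the inputs; `NA` where invalid.
#' @examples
#' computeEVI(0.05, 0.1, 0.4)
#' computeEVI(0.1, 0.3, 0.3)  # NIR = Red: exactly 0
#' @export
computeEVI <- function(blue, red, nir) {
  den <- nir + .EVI_C1 * red - .EVI_C2 * blue + .EVI_L
  out <- .EVI_G * (nir - red) / den
  out[abs(den) < .Machine$double.eps^0.5] <- NA_real_
  out[!is.na(out) & (out < .EVI_RANGE[1] | out > .EVI_RANGE[2])] <- NA_real_
  out
}

#' Normalized difference infrared index
#'
#' NDII = (NIR - SWIR1) / (NIR + SWIR1), a canopy-moisture index using the
#' 1.55-1.75 um shortwave-infrared band. Vectorized; `NA` inputs and a zero
#' sum (both reflectances zero) yield `NA`.
#'
#' @param nir,swir1 Surface reflectances in `[0, 1]`.
#' @return The NDII in `[-1, 1]`, same shape as the inputs; `NA` where
#'   invalid.
#' @examples
#' computeNDII(0.4, 0.2)
#' @export
computeNDII <- function(nir, swir1) {
  den <- nir + swir1
  out <- (nir - swir1) / den
  out[abs(den) < .Machine$double.eps^0.5] <- NA_real_
  out
}

#' Mask cloud and water observations
#'
#' Sets every reflectance band to `NA` where the stack's `qa` layer flags the
#' observation as cloud (1) or water (2); clear observations are untouched.
#' Idempotent. Per-date counts of newly dropped observations are recorded in
#' `metadata(x)$maskedCounts` and reported via `message()`.
#'
#' @param x A [ReflectanceStack-class] with a `qa` assay.
#' @param quiet Suppress the per-stack message.
#' @return The masked [ReflectanceStack-class].
#' @export
applyQAMask <- function(x, quiet = FALSE) {
  if (!"qa" %in% assayNames(x))
    stop("stack has no qa layer; cannot mask")
  qa <- assay(x, "qa")
  bad <- qa != 0L
  dropped <- integer(ncol(qa))
  a <- assays(x)
  for (b in .stack_bands) {
    m <- a[[b]]
    newly <- bad & !is.na(m)
    dropped <- dropped + colSums(newly)
    m[bad] <- NA_real_
    a[[b]] <- m
  }
  assays(x) <- a
  metadata(x)$maskedCounts <- data.frame(
    timestamp = obsTime(x), year = obsYear(x),
    dropped = as.integer(dropped / length(.stack_bands))
  )
  if (!quiet)
    message(sprintf("applyQAMask: masked %d of %d observations (%d dates)",
      sum(bad), length(bad), ncol(qa)))
  x
}

#' Compute the EVI and NDII tracks for a whole stack
#'
#' Applies [computeEVI()] and [computeNDII()] to every pixel and date of a
#' (typically already QA-masked) reflectance stack.
#'
#' @param stack A [ReflectanceStack-class].
#' @return An [IndexStack-class] with assays `evi` and `ndii`; invalid
#'   observations are `NA`.
#' @export
computeIndices <- function(stack) {
  evi <- computeEVI(assay(stack, "blue"), assay(stack, "red"),
                    assay(stack, "nir"))
  ndii <- computeNDII(assay(stack, "nir"), assay(stack, "swir1"))
  se <- SummarizedExperiment(
    assays = list(evi = evi, ndii = ndii),
    rowData = rowData(stack), colData = colData(stack)
  )
  out <- new("IndexStack", se)
  metadata(out) <- metadata(stack)
  out
}
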