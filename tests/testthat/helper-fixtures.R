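# Shared fixtures built in code.

# Independent brute-force oracle for Sen's slope: explicit double loop over
# all pairs, median of the collected pairwise slopes.
bruteSenOracle <- function(x, y) {
  slopes <- numeric()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  }
  stats::median(slopes)
}

# Build a ReflectanceStack whose EVI and NDII equal the given matrices
# exactly, by inverting the index formulas (blue/red held constant, NIR then
# SWIR1 solved). qa defaults to all-clear.
stackFromIndices <- function(evi, ndii, timestamp, year, qa = NULL) {
  npx <- nrow(evi); nd <- ncol(evi)
  nir <- (0.25 + 1.225 * evi) / (2.5 - evi)
  swir1 <- nir * (1 - ndii) / (1 + ndii)
  if (is.null(qa)) qa <- matrix(0L, npx, nd)
  reflectanceStack(
    blue = matrix(0.05, npx, nd), red = matrix(0.10, npx, nd),
    nir = nir, swir1 = swir1, qa = qa,
    timestamp = timestamp, year = year
  )
}

# IndexStack straight from index matrices (via exact inversion + recompute).
indexStackFrom <- function(evi, ndii, timestamp, year, qa = NULL) {
  computeIndices(applyQAMask(
    stackFromIndices(evi, ndii, timestamp, year, qa), quiet = TRUE))
}

# A minimal valid PA-table row.
paRow <- function(id, status, state = "S01", area = 100, rain = 1500,
                  decl = NA_integer_, xmin = 0, ymin = 0, w = 10e3, h = 10e3) {
  data.frame(id = id, name = id, status = status, state = state,
             area_km2 = area, rainfall_mm = rain,
             declaration_year = as.integer(decl),
             xmin = xmin, ymin = ymin, xmax = xmin + w, ymax = ymin + h,
             stringsAsFactors = FALSE)
}
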