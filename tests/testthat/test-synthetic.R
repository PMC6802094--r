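test_that("PA table generator honours its contract", {
  # empty case
  empty <- generatePATable(1, 0, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "status", "state", "area_km2", "rainfall_mm",
                    "declaration_year", "xmin", "ymax") %in% names(empty)))
  # determinism
  a <- generatePATable(2, 2, 6, seed = 7)
  b <- generatePATable(2, 2, 6, seed = 7)
  expect_identical(a, b)
  # draws stay within the generator's configured ranges
  rr <- attr(a, "rainfallRange")
  expect_true(all(a$rainfall_mm >= rr[1] & a$rainfall_mm <= rr[2]))
  expect_true(all(a$area_km2 > 0))
  dr <- attr(a, "declarationRange")
  decl <- a$declaration_year[a$status == "TR"]
  expect_true(all(decl >= dr[1] & decl <= dr[2]))
  # rectangle area is consistent with the attribute
  expect_equal((a$xmax - a$xmin) * (a$ymax - a$ymin) / 1e6, a$area_km2,
               tolerance = 1e-9)
  # at least one eligible control per state when nWLS >= nStates
  wls <- a[a$status == "WLS", ]
  expect_true(all(tapply(wls$area_km2, wls$state, max) >= 75))
  expect_error(generatePATable(0, 1, 1, seed = 1), "nStates")
  expect_error(generatePATable(1, -1, 1, seed = 1), ">= 0")
})

test_that("scene generation is reproducible byte-for-byte", {
  spec <- sceneSpec(5, 4, years = c(1990, 2000), obsPerYear = 8,
                    cloudFraction = 0.1, noiseSD = 0.01, seed = 9)
  s1 <- simulateStack(spec, simulateTruth(spec, 1995))
  s2 <- simulateStack(spec, simulateTruth(spec, 1995))
  expect_identical(serialize(bandValues(s1$stack, "nir"), NULL),
                   serialize(bandValues(s2$stack, "nir"), NULL))
  expect_identical(serialize(bandValues(s1$stack, "qa"), NULL),
                   serialize(bandValues(s2$stack, "qa"), NULL))
  expect_identical(trueSlopes(s1$truth), trueSlopes(s2$truth))
})

test_that("masked-observation fraction matches the configured rates", {
  spec <- sceneSpec(12, 12, years = c(1990, 2000), obsPerYear = 10,
                    cloudFraction = 0.15, waterFraction = 0.05, seed = 10)
  sim <- simulateStack(spec, simulateTruth(spec, 1995))
  qa <- bandValues(sim$stack, "qa")
  p <- 0.20
  n <- length(qa)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(qa != 0) - p), 2 * se + 1e-12)
})

test_that("truth categories are consistent with the classification rules", {
  spec <- sceneSpec(6, 6, years = c(1984, 2012), obsPerYear = 6, seed = 11)
  truth <- simulateTruth(spec, 1993)
  s <- trueSlopes(truth)
  expect_identical(trueCondition(truth, "after"),
                   classifyAfter(s[, "b_after"], s[, "d_after"]))
  expect_identical(trueCondition(truth, "change"),
                   classifyChange(s[, "b_before"], s[, "b_after"],
                                  s[, "d_before"], s[, "d_after"]))
  expect_error(validObject(truth), NA)
})

test_that("planted category fractions are realized exactly", {
  spec <- sceneSpec(10, 10, years = c(1984, 2012), obsPerYear = 6, seed = 12)
  truth <- simulateTruth(spec, 1993,
                         fractions = c(helped = 0.6, harmed = 0.25,
                                       unclear = 0.15))
  tab <- table(trueCondition(truth, "change"))
  expect_equal(as.numeric(tab[c("helped", "harmed", "unclear")]),
               c(60, 25, 15))
})

test_that("planted index values survive the reflectance inversion round trip", {
  spec <- sceneSpec(3, 3, years = c(1990, 1999), obsPerYear = 10, seed = 13)
  sim <- simulateStack(spec, simulateTruth(spec, 1995))
  st <- sim$stack
  evi <- computeEVI(bandValues(st, "blue"), bandValues(st, "red"),
                    bandValues(st, "nir"))
  ndii <- computeNDII(bandValues(st, "nir"), bandValues(st, "swir1"))
  # reconstruct the planted trough line for one pixel and compare at the
  # trough observations (least values of each year)
  comp <- buildComposites(computeIndices(applyQAMask(st, quiet = TRUE)))
  s <- trueSlopes(sim$truth)
  v <- bandValues(comp, "evi")[1, ]
  ts <- bandValues(comp, "eviTime")[1, ]
  tb <- 1995 - 1984
  expected <- ifelse(ts < tb,
    sim$truth@baseEVI[1] + s[1, "b_before"] * ts,
    sim$truth@baseEVI[1] + s[1, "b_before"] * tb + s[1, "b_after"] * (ts - tb))
  expect_equal(v, expected, tolerance = 1e-9)
  expect_true(all(abs(ndii) <= 1, na.rm = TRUE))
  expect_true(all(evi >= -1 & evi <= 2, na.rm = TRUE))
})

test_that("a fully clouded scene leaves every pixel insufficient downstream", {
  spec <- sceneSpec(3, 3, years = c(1990, 2000), obsPerYear = 6,
                    cloudFraction = 1, seed = 14)
  sim <- simulateStack(spec, simulateTruth(spec, 1995))
  comp <- buildComposites(computeIndices(applyQAMask(sim$stack, quiet = TRUE)))
  sm <- estimateEpochSlopes(comp, 1995)
  expect_true(all(is.na(slopeMatrix(sm))))
  expect_true(all(classifyPixels(sm, "after") == "insufficient"))
})
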