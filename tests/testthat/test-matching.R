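test_that("candidate controls respect state, area and rainfall constraints", {
  tr <- paRow("TR01", "TR", state = "S01", rain = 1200, decl = 1995)
  tab <- rbind(
    tr,
    paRow("WLS01", "WLS", state = "S01", area = 100, rain = 1500),
    paRow("WLS02", "WLS", state = "S01", area = 100, rain = 1900),  # |d| = 700
    paRow("WLS03", "WLS", state = "S01", area = 74, rain = 1200),   # too small
    paRow("WLS04", "WLS", state = "S02", area = 100, rain = 1200),  # other state
    paRow("WLS05", "WLS", state = "S01", area = 75, rain = 1700)    # |d| = 500
  )
  cand <- candidateWLS(tr, tab)
  expect_setequal(cand$id, c("WLS01", "WLS05"))  # inclusive 75 km2 and 500 mm
})

test_that("separation distance handles overlap, gaps and centroids", {
  a <- paRow("A", "TR", xmin = 0, ymin = 0, w = 10e3, h = 10e3)
  b <- paRow("B", "WLS", xmin = 5e3, ymin = 5e3, w = 10e3, h = 10e3)
  expect_equal(separationDistance(a, b), 0)  # overlapping
  c2 <- paRow("C", "WLS", xmin = 20e3, ymin = 0, w = 10e3, h = 10e3)
  expect_equal(separationDistance(a, c2), 10)  # 10 km edge-to-edge
  d <- paRow("D", "WLS", xmin = 13e3, ymin = 14e3, w = 10e3, h = 10e3)
  expect_equal(separationDistance(a, d), 5)  # 3-4-5 corner gap
  expect_equal(separationDistance(a, c2, metric = "centroid"), 20)
  bad <- a; bad$xmax <- -1
  expect_error(separationDistance(bad, b), "geometry")
})

test_that("PA rainfall is the area-weighted annual sum over the grid", {
  uniformGrid <- list(
    monthly = array(100, c(2, 2, 12)), origin = c(0, 0), cellSize = 10e3)
  pa <- paRow("A", "TR", xmin = 2e3, ymin = 2e3, w = 12e3, h = 5e3)
  expect_equal(paMeanRainfall(pa, uniformGrid), 1200)
  # polygon entirely inside one cell
  ann <- array(0, c(1, 2, 12)); ann[1, 1, ] <- 1000 / 12; ann[1, 2, ] <- 2000 / 12
  grid <- list(monthly = ann, origin = c(0, 0), cellSize = 10e3)
  inOne <- paRow("B", "TR", xmin = 1e3, ymin = 1e3, w = 5e3, h = 5e3)
  expect_equal(paMeanRainfall(inOne, grid), 1000)
  # 50/50 straddle of two cells with annual sums 1000 and 2000
  straddle <- paRow("C", "TR", xmin = 5e3, ymin = 0, w = 10e3, h = 8e3)
  expect_equal(paMeanRainfall(straddle, grid), 1500)
  outside <- paRow("D", "TR", xmin = 100e3, ymin = 0, w = 5e3, h = 5e3)
  expect_error(paMeanRainfall(outside, grid), "cover")
})

test_that("each TR takes its nearest candidate; conflicts fall to next-nearest", {
  tr <- paRow("TR01", "TR", rain = 1200, decl = 1995, xmin = 0)
  near <- paRow("WLS01", "WLS", rain = 1300, xmin = 50e3)   # 40 km away
  far <- paRow("WLS02", "WLS", rain = 1300, xmin = 100e3)   # 90 km away
  m <- matchPairs(rbind(tr, near, far))
  expect_equal(m$pairs$wls_id, "WLS01")
  expect_equal(m$pairs$separation_km, 40)
  expect_length(m$unmatched, 0)

  # two TRs share a nearest WLS: the earlier-declared keeps it
  tr2 <- paRow("TR02", "TR", rain = 1200, decl = 1990, xmin = 100e3 + 10e3 + 30e3)
  m2 <- matchPairs(rbind(tr, tr2, near, far))
  expect_equal(m2$pairs$wls_id[m2$pairs$tr_id == "TR02"], "WLS02")  # decl 1990 first, nearest is WLS02
  expect_equal(m2$pairs$wls_id[m2$pairs$tr_id == "TR01"], "WLS01")
  expect_false(any(duplicated(m2$pairs$wls_id)))

  # a TR with zero candidates is reported unmatched
  lonely <- paRow("TR03", "TR", state = "S09", rain = 1200, decl = 2000)
  m3 <- matchPairs(rbind(lonely, near))
  expect_equal(m3$unmatched, "TR03")
  expect_equal(nrow(m3$pairs), 0)
})

test_that("contested nearest WLS goes to the first-processed TR, other takes next-nearest", {
  # both TRs nearest to WLS01; TR early (decl 1990) processed first
  trE <- paRow("TRE", "TR", rain = 1200, decl = 1990, xmin = 0)
  trL <- paRow("TRL", "TR", rain = 1200, decl = 2000, xmin = 40e3)
  wNear <- paRow("WLS01", "WLS", rain = 1250, xmin = 22e3)  # nearest to both
  wNext <- paRow("WLS02", "WLS", rain = 1250, xmin = 70e3)
  m <- matchPairs(rbind(trE, trL, wNear, wNext))
  expect_equal(m$pairs$wls_id[m$pairs$tr_id == "TRE"], "WLS01")
  expect_equal(m$pairs$wls_id[m$pairs$tr_id == "TRL"], "WLS02")
})

test_that("every emitted pair satisfies all matching constraints on random tables", {
  cfg <- analysisConfig()
  for (seed in 1:20) {
    tab <- generatePATable(nStates = 3, nTR = 4, nWLS = 9, seed = seed)
    m <- matchPairs(tab, cfg)
    expect_false(any(duplicated(m$pairs$wls_id)))  # injective on WLSs
    for (i in seq_len(nrow(m$pairs))) {
      tr <- tab[tab$id == m$pairs$tr_id[i], ]
      wls <- tab[tab$id == m$pairs$wls_id[i], ]
      expect_identical(tr$state, wls$state)
      expect_gte(wls$area_km2, cfg@wlsMinArea)
      expect_lte(abs(tr$rainfall_mm - wls$rainfall_mm), cfg@rainfallWindow)
    }
  }
})
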