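test_that("after-epoch classification covers all 9 sign combinations", {
  s <- c(-0.003, 0, 0.004)
  grid <- expand.grid(b = s, d = s)
  got <- classifyAfter(grid$b, grid$d)
  want <- ifelse(grid$b > 0 & grid$d > 0, "improve",
          ifelse(grid$b < 0 & grid$d < 0, "decline", "unclear"))
  expect_identical(as.character(got), want)
  # worked examples
  expect_equal(as.character(classifyAfter(0.004, 0.002)), "improve")
  expect_equal(as.character(classifyAfter(-0.003, -0.001)), "decline")
  expect_equal(as.character(classifyAfter(0.004, -0.001)), "unclear")
  # missing slope -> insufficient
  expect_equal(as.character(classifyAfter(NA, 0.1)), "insufficient")
})

test_that("change classification covers all 9 sign combinations of differences", {
  d <- c(-0.002, 0, 0.003)
  grid <- expand.grid(db = d, dd = d)
  got <- classifyChange(rep(0.001, 9), 0.001 + grid$db,
                        rep(-0.001, 9), -0.001 + grid$dd)
  want <- ifelse(grid$db > 0 & grid$dd > 0, "helped",
          ifelse(grid$db < 0 & grid$dd < 0, "harmed", "unclear"))
  expect_identical(as.character(got), want)
  expect_equal(as.character(classifyChange(0.001, 0.003, 0.001, 0.002)),
               "helped")
  expect_equal(as.character(classifyChange(0.002, 0.001, 0.002, 0.000)),
               "harmed")
  expect_equal(as.character(classifyChange(0.002, 0.001, 0.000, 0.001)),
               "unclear")
  expect_equal(as.character(classifyChange(NA, 0.1, 0.1, 0.2)),
               "insufficient")
})

test_that("composition reports percentages over all PA pixels and sums to 100", {
  cats <- factor(rep(c("improve", "decline", "unclear"), c(50, 30, 20)),
                 levels = c("improve", "decline", "unclear", "insufficient"))
  cs <- composition(cats, paId = "PA1")
  expect_equal(cs$improve, 50)
  expect_equal(cs$decline, 30)
  expect_equal(cs$unclear, 20)
  expect_equal(cs$insufficient, 0)
  expect_equal(cs$improve + cs$decline + cs$unclear + cs$insufficient, 100)
  one <- composition(factor(rep("decline", 10),
                            levels = levels(cats)), paId = "PA2")
  expect_equal(one$decline, 100)
  # masked subset is the denominator
  mask <- rep(c(TRUE, FALSE), c(60, 40))
  sub <- composition(cats, paMask = mask, paId = "PA3")
  expect_equal(sub$n_pixels, 60)
  expect_equal(sub$improve, 100 * 50 / 60)
  # a PA dropped by the sufficiency rule is refused
  expect_error(composition(cats, paId = "PA4", sufficient = FALSE), "dropped")
})

test_that("pair comparison applies the simultaneity and 15%-substantiality rules", {
  mk <- function(id, imp, dec) {
    data.frame(pa_id = id, mode = "after", improve = imp, decline = dec,
               unclear = 100 - imp - dec, insufficient = 0, n_pixels = 100)
  }
  cfg <- analysisConfig()
  better <- comparePair(mk("TR", 40, 30), mk("WLS", 20, 50), cfg)
  expect_equal(better$verdict, "better")
  expect_true(better$substantial)
  worse <- comparePair(mk("TR", 20, 50), mk("WLS", 40, 30), cfg)
  expect_equal(worse$verdict, "worse")
  expect_true(worse$substantial)
  amb <- comparePair(mk("TR", 40, 50), mk("WLS", 20, 30), cfg)
  expect_equal(amb$verdict, "ambiguous")
  # below the 15-point threshold on both axes
  mild <- comparePair(mk("TR", 30, 30), mk("WLS", 20, 40), cfg)
  expect_equal(mild$verdict, "better")
  expect_false(mild$substantial)
  # exactly 15 points is substantial (inclusive rule)
  edge <- comparePair(mk("TR", 35, 30), mk("WLS", 20, 31), cfg)
  expect_true(edge$substantial)
  expect_error(comparePair(mk("TR", 1, 1),
                           within(mk("WLS", 1, 1), mode <- "change")),
               "modes")
})

test_that("swapping the pair maps better to worse and fixes ambiguous", {
  mk <- function(id, imp, dec) {
    data.frame(pa_id = id, mode = "after", improve = imp, decline = dec,
               unclear = 100 - imp - dec, insufficient = 0, n_pixels = 100)
  }
  set.seed(41)
  flip <- c(better = "worse", worse = "better", ambiguous = "ambiguous")
  for (i in 1:40) {
    a <- mk("A", runif(1, 0, 60), runif(1, 0, 40))
    b <- mk("B", runif(1, 0, 60), runif(1, 0, 40))
    ab <- comparePair(a, b)
    ba <- comparePair(b, a)
    expect_identical(ba$verdict, unname(flip[ab$verdict]))
    expect_identical(ba$substantial, ab$substantial)
  }
})

test_that("ternary export renormalizes over the three analysed categories", {
  cats <- factor(rep(c("improve", "decline", "unclear"), c(50, 30, 20)),
                 levels = c("improve", "decline", "unclear", "insufficient"))
  cs <- composition(cats, paId = "PA1")
  tern <- ternaryExport(cs)
  expect_equal(unlist(tern[1, c("improve", "decline", "unclear")]),
               c(improve = 0.5, decline = 0.3, unclear = 0.2))
  # 10% insufficient renormalized over the remaining 90%
  cats2 <- factor(rep(c("improve", "decline", "unclear", "insufficient"),
                      c(45, 27, 18, 10)), levels = levels(cats))
  tern2 <- ternaryExport(composition(cats2, paId = "PA2"))
  expect_equal(sum(tern2[1, -1]), 1)
  expect_equal(tern2$improve, 45 / 90)
  expect_equal(nrow(ternaryExport(data.frame())), 0)
})
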