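test_that("degenerate population frequencies give the degenerate pools", {
  near0 <- QpcrParams(sigmaC = 1e-9)
  d0 <- simulateBulkCq(SimDesign(p = 0, k = 1, nPerSample = 8, nSamples = 20,
                                 params = near0), seed = 1L)
  lat <- latentState(d0)
  expect_true(all(lat$m == 0L) && all(lat$xR == 0))
  ## all-S pools sit at the z-floor of the ddCq curve, about 9.52 cycles at
  ## the calibrated assay values
  expect_equal(deltaCq(d0)$ddtau,
               rep(theoreticalDdcq(0, 0.0016, 0.97), 20), tolerance = 1e-5)

  d1 <- simulateBulkCq(SimDesign(p = 1, k = 1, nPerSample = 8, nSamples = 20,
                                 params = near0), seed = 2L)
  expect_true(all(latentState(d1)$xS == 0))
  expect_equal(deltaCq(d1)$ddtau, rep(0, 20), tolerance = 1e-5)
})

test_that("in the noise-free limit the observed ddCq is the theoretical curve", {
  des <- SimDesign(p = 0.4, k = 2, nPerSample = 6, nSamples = 30,
                   params = QpcrParams(sigmaC = 1e-9))
  d <- simulateBulkCq(des, seed = 3L)
  expect_equal(deltaCq(d)$ddtau,
               theoreticalDdcq(latentState(d)$yR, 0.0016, 0.97),
               tolerance = 1e-5)
})

test_that("simulated DNA amounts have the designed moments", {
  des <- SimDesign(p = 0.5, k = 3, nPerSample = 8, nSamples = 1e5L)
  d <- simulateBulkCq(des, seed = 4L)
  lat <- latentState(d)
  tot <- lat$xR + lat$xS
  ## mean total per pool is n * meanYield; compare within 3 SE
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 8e-6), 3 * se)
  ## carrier counts are binomial
  expect_lt(abs(mean(lat$m) - 4), 3 * sd(lat$m) / sqrt(length(lat$m)))
})

test_that("simulation is deterministic in the seed", {
  des <- SimDesign(p = 0.2, k = 1, nPerSample = 4, nSamples = 6)
  a <- simulateBulkCq(des, seed = 99L)
  b <- simulateBulkCq(des, seed = 99L)
  expect_identical(cqValues(a), cqValues(b))
  expect_false(identical(cqValues(a),
                         cqValues(simulateBulkCq(des, seed = 100L))))
})

test_that("rule-of-three threshold", {
  expect_equal(ruleOfThree(0.05), 60)
  expect_equal(ruleOfThree(1), 3)
  expect_equal(ruleOfThree(0.001), 3000)
  expect_error(ruleOfThree(0), "0 < p")
})

test_that("the default design grid enumerates 624 regions", {
  g <- gridDesigns()
  expect_identical(nrow(g), 624L)
  expect_true(all(g$ntotal >= 4 & g$ntotal <= 128))
  expect_identical(sort(unique(g$p)), c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75))
  expect_identical(sort(unique(g$k)), c(1, 3, 9, 27))
  ## 26 sampling layouts per (p, k) combination
  expect_identical(nrow(unique(g[, c("N", "n")])), 26L)
  expect_identical(g$ruleOfThree, g$ntotal > 3 / g$p)
})

test_that("the grid harness records every fit attempt and pools quantiles", {
  g <- gridDesigns()[c(30, 300), ]
  r <- runGrid(g, replicates = 5L, seed = 17L)
  expect_identical(nrow(r$replicates), 10L)
  expect_identical(nrow(r$summary), 2L)
  expect_true(all(r$summary$successRate >= 0 & r$summary$successRate <= 1))
  expect_true(all(c("pHatMed", "pLowerMed", "pUpperMed", "convMed")
                  %in% names(r$summary)))
  ## deterministic given (design, seed)
  r2 <- runGrid(g, replicates = 5L, seed = 17L)
  expect_identical(r$replicates$pHat, r2$replicates$pHat)
})

test_that("known-ratio simulator honours the requested layout", {
  d <- simulateKnownRatio(miteParams(), seed = 8L)
  df <- as.data.frame(d)
  expect_identical(nrow(df), 88L)   # 10 ratios x 2 genes x 4 reps + 8 pure-R
  expect_true(all(df$ratio[df$condition == 0] == 1))
  full <- simulateKnownRatio(miteParams(), ratio = c(0, 0.5, 1),
                             undigestedRatios = c(0, 0.5, 1),
                             replicates = 2, seed = 9L)
  expect_identical(nrow(as.data.frame(full)), 24L)
})
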