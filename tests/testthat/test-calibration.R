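test_that("known-ratio Cq means follow the closed-form model", {
  p <- miteParams()
  L <- log(1 + 0.9712)
  ## pure-R: digestion leaves the target ratio at 1, so both conditions give
  ## the same target-minus-housekeeping difference, -ln(deltaT)/L
  d10 <- knownCqMean(p, 1, "target", 1) - knownCqMean(p, 1, "housek", 1)
  d00 <- knownCqMean(p, 1, "target", 0) - knownCqMean(p, 1, "housek", 0)
  expect_equal(d10, d00)
  expect_equal(d10, -log(1.170) / L)

  ## pure-S digested: the residue rate sets the whole signal
  pz <- QpcrParams(eta = 0.9712, deltaT = 1, deltaB = 1, z = 0.001564,
                   meanDNA = 1.256e-6)
  expect_equal(knownCqMean(pz, 0, "target", 1) - knownCqMean(pz, 0, "housek", 1),
               -log(0.001564) / L, tolerance = 1e-12)
  expect_equal(knownCqMean(pz, 1, "housek", 0), -log(1.256e-6) / L,
               tolerance = 1e-12)
  expect_equal(knownCqMean(pz, 1, "housek", 0), 20.02, tolerance = 1e-3)
  expect_error(knownCqMean(p, -0.1, "target", 1), "\\[0, 1\\]")
})

test_that("noise-free known-ratio data is recovered exactly", {
  truth <- QpcrParams(eta = 0.9, deltaT = 1.3, deltaB = 0.3, z = 0.002,
                      sigmaC = 0.25, meanDNA = 2e-6)
  grid <- expand.grid(ratio = c(0, 0.01, 0.1, 0.5, 1),
                      gene = c("housek", "target"), condition = 0:1,
                      replicate = "r1", stringsAsFactors = FALSE)
  d <- KnownRatioData(grid$ratio, grid$gene, grid$condition, grid$replicate,
                      cq = knownCqMean(truth, grid$ratio, grid$gene,
                                       grid$condition))
  fit <- calibrateKnown(d, paired = TRUE)
  est <- coef(fit)
  for (nm in c("meanDNA", "deltaT", "deltaB", "z", "eta"))
    expect_equal(est[[nm]], slot(truth, switch(nm, meanDNA = "meanDNA",
                                               deltaT = "deltaT",
                                               deltaB = "deltaB",
                                               z = "z", eta = "eta")),
                 tolerance = 1e-6)
  expect_lt(est[["sigmaC"]], 1e-4)   # zero-residual optimum
  ## round trip: the fitted model reproduces the noiseless table
  refit <- QpcrParams(eta = est[["eta"]], deltaT = est[["deltaT"]],
                      deltaB = est[["deltaB"]], z = est[["z"]],
                      sigmaC = 0.1, meanDNA = est[["meanDNA"]])
  expect_equal(knownCqMean(refit, grid$ratio, grid$gene, grid$condition),
               d@data$cq, tolerance = 1e-5)
})

test_that("calibration is invariant to observation order", {
  d <- simulateKnownRatio(miteParams(), seed = 31L)
  df <- as.data.frame(d)
  f1 <- calibrateKnown(d)
  f2 <- calibrateKnown(df[sample.int(nrow(df)), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("unpaired mite-layout data yields all six parameters with CIs", {
  d <- simulateKnownRatio(miteParams(), seed = 91L)
  ## layout: undigested rows only at ratio 1
  df <- as.data.frame(d)
  expect_true(all(df$ratio[df$condition == 0] == 1))
  fit <- calibrateKnown(d, paired = FALSE)
  expect_true(fit@converged)
  expect_true(fitSuccess(fit))
  ci <- confint(fit)
  expect_true(all(is.finite(ci)))
  ## log-scale Wald intervals are multiplicatively symmetric
  expect_equal(ci[, "upper"] / coef(fit), coef(fit) / ci[, "lower"],
               tolerance = 1e-6)
  ## paired mode refuses the incomplete layout
  expect_error(calibrateKnown(d, paired = TRUE), "complete")
})

test_that("identifiability failures are reported with the parameter name", {
  p <- miteParams()
  d1 <- simulateKnownRatio(p, ratio = 1, undigestedRatios = 1, seed = 1L)
  expect_error(calibrateKnown(d1), "z")
  df <- as.data.frame(simulateKnownRatio(p, seed = 2L))
  expect_error(calibrateKnown(df[df$condition == 1, ]), "meanDNA|deltaB")
})

test_that("parameter coverage of the calibration CIs is near nominal", {
  truth <- miteParams()
  tv <- c(meanDNA = 1.256e-6, deltaT = 1.170, deltaB = 0.2361,
          sigmaC = 0.2376, z = 0.001564, eta = 0.9712)
  hits <- matrix(0L, 0, 6, dimnames = list(NULL, names(tv)))
  nOK <- 0L
  for (r in 1:100) {
    d <- simulateKnownRatio(truth, seed = 1000L + r)
    fit <- tryCatch(calibrateKnown(d), error = function(e) NULL)
    if (is.null(fit) || !fitSuccess(fit)) next
    nOK <- nOK + 1L
    ci <- confint(fit)[names(tv), ]
    hits <- rbind(hits, as.integer(ci[, "lower"] <= tv & tv <= ci[, "upper"]))
  }
  expect_gt(nOK, 90L)
  cov <- colMeans(hits)
  ## nominal 95%; with 100 replicates allow a wide Monte-Carlo margin
  expect_true(all(cov >= 0.86 & cov <= 1), info = paste(round(cov, 3),
                                                        collapse = " "))
})

test_that("linearity diagnostics recover an exact line and match bptest", {
  truth <- miteParams()
  ## noise-free data: observed ddCq equals the theoretical predictor exactly
  d0 <- simulateKnownRatio(QpcrParams(eta = 0.9712, deltaT = 1.170,
                                      deltaB = 0.2361, z = 0.001564,
                                      sigmaC = 1e-12, meanDNA = 1.256e-6),
                           seed = 5L)
  diag0 <- linearityDiagnostics(d0, z = 0.001564, eta = 0.9712)
  expect_equal(diag0$slope, 1, tolerance = 1e-4)
  expect_equal(diag0$intercept, 0, tolerance = 1e-4)
  expect_gt(diag0$adjR2, 0.999999)
  expect_lt(diag0$bp, 1e-6)

  ## noisy data: the LM-form statistic equals the studentized Breusch-Pagan
  dn <- simulateKnownRatio(truth, seed = 6L)
  for (sc in c("ddcq", "linear")) {
    dg <- linearityDiagnostics(dn, z = 0.001564, eta = 0.9712, scale = sc)
    ref <- lmtest::bptest(dg$model)
    expect_equal(dg$bp, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(dg$bpP, unname(ref$p.value), tolerance = 1e-8)
    expect_identical(dg$bpDf, 1L)
  }
  expect_error(linearityDiagnostics(as.data.frame(dn)[1:8, ], 0.0016, 0.97),
               "3")
})
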