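test_that("Wald intervals from the observed information behave", {
  ## 1-D: curvature c gives SE 1/sqrt(c)
  ci <- ciFromHessian(0.3, matrix(4), level = 0.95)
  expect_equal(ci$se, 0.5)
  expect_equal(ci$lower, 0.3 - qnorm(0.975) * 0.5)
  expect_true(ci$success)

  ## diagonal case matches independent 1-D formulas
  ci2 <- ciFromHessian(c(0, 1), diag(c(4, 25)))
  expect_equal(ci2$se, c(0.5, 0.2))
  expect_equal(ci2$upper, c(0, 1) + qnorm(0.975) * c(0.5, 0.2))

  ## a negative diagonal of the inverse flags that parameter, not an error
  ci3 <- ciFromHessian(c(0, 0), diag(c(2, -1)))
  expect_false(ci3$success)
  expect_equal(ci3$paramSuccess, c(TRUE, FALSE))
  expect_true(is.na(ci3$lower[2]) && is.finite(ci3$lower[1]))

  ## singular matrix: no interval anywhere, still no exception
  ci4 <- ciFromHessian(c(0, 0), matrix(1, 2, 2))
  expect_false(ci4$success)
})

test_that("near noise-free data recovers the empirical pool frequency", {
  des <- SimDesign(p = 0.5, k = 1, nPerSample = 8, nSamples = 32,
                   params = QpcrParams(sigmaC = 0.02))
  d <- simulateBulkCq(des, seed = 404L)
  ## a denser quadrature rule: the near-noise-free likelihood is sharper
  ## than the default panel resolution tuned to assay-scale Cq noise
  fit <- estimateFreq(d, z = 0.0016, eta = 0.97, quadNodes = 32L)
  empirical <- sum(latentState(d)$m) / sum(poolSize(d))
  expect_true(fit@converged)
  expect_lt(abs(coef(fit)[["p"]] - empirical), 0.05)
})

test_that("estimates are invariant to sample order", {
  d <- smallBulk(N = 8L, n = 8L, p = 0.2, seed = 77L)
  fit1 <- estimateFreq(d, z = 0.0016, eta = 0.97)
  fit2 <- estimateFreq(d[c(5, 2, 8, 1, 7, 3, 6, 4)], z = 0.0016, eta = 0.97)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
})

test_that("fixing k = 1 scarcely moves the frequency estimate", {
  d <- simulateBulkCq(SimDesign(p = 0.25, k = 1, nPerSample = 8,
                                nSamples = 16), seed = 505L)
  free <- estimateFreq(d, z = 0.0016, eta = 0.97)
  fixed <- estimateFreq(d, z = 0.0016, eta = 0.97, fixK = 1)
  expect_false("k" %in% names(coef(fixed)))
  expect_lt(abs(coef(free)[["p"]] - coef(fixed)[["p"]]), 0.05)
  ## the p interval respects the unit range by construction
  expect_true(all(confint(free)["p", ] >= 0 & confint(free)["p", ] <= 1))
})

test_that("gamma and beta kernels give equivalent fits", {
  d <- smallBulk(N = 6L, n = 4L, p = 0.3, seed = 66L)
  fb <- estimateFreq(d, z = 0.0016, eta = 0.97, fixK = 1)
  fg <- estimateFreq(d, z = 0.0016, eta = 0.97, fixK = 1, kernel = "gamma")
  expect_equal(coef(fb)[["p"]], coef(fg)[["p"]], tolerance = 0.02)
})

test_that("undersized designs usually fail interval estimation", {
  ## Nn = 8 against a 1% allele: far below the rule-of-three threshold (300)
  fails <- 0L
  for (r in 1:20) {
    d <- simulateBulkCq(SimDesign(p = 0.01, k = 1, nPerSample = 4,
                                  nSamples = 2), seed = 600L + r)
    fit <- tryCatch(estimateFreq(d, z = 0.0016, eta = 0.97),
                    error = function(e) NULL)
    if (is.null(fit) || !fitSuccess(fit)) fails <- fails + 1L
  }
  expect_gt(fails, 10L)
})

test_that("successful fits expose finite intervals and fit metadata", {
  d <- smallBulk(N = 8L, n = 8L, p = 0.3, seed = 88L)
  fit <- estimateFreq(d, z = 0.0016, eta = 0.97)
  if (fitSuccess(fit)) {
    ci <- confint(fit)
    expect_true(all(is.finite(ci)))
    expect_true(all(ci[, "lower"] <= coef(fit) & coef(fit) <= ci[, "upper"]))
  }
  expect_s4_class(fit, "FreqFit")
  expect_identical(fit@fixed[["z"]], 0.0016)
  df <- as.data.frame(fit)
  expect_identical(df$parameter, c("p", "k", "deltaT", "sigmaC"))
  expect_error(estimateFreq(deltaCq(d)[1, , drop = FALSE], z = 1, eta = 1),
               "dtauW|two")
})
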