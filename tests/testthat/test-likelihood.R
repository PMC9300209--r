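test_that("control delta-Cq log-density is the stated normal", {
  ## at the mode the density of N(mu, 2 sigma^2) is 1/(sigma sqrt(4 pi))
  expect_equal(dtauWLogDensity(0, deltaT = 1, eta = 0.97, sigmaC = 0.2),
               log(1 / (0.2 * sqrt(4 * pi))))
  ## deltaT = 1 centres the density at 0 whatever the efficiency
  for (eta in c(0.5, 0.9, 1)) {
    g <- dtauWLogDensity(c(-0.1, 0.1), deltaT = 1, eta = eta, sigmaC = 0.3)
    expect_equal(g[1], g[2])
  }
  ## integrates to one
  ii <- integrate(function(x)
    exp(dtauWLogDensity(x, deltaT = 1.2, eta = 0.97, sigmaC = 0.2)),
    -Inf, Inf)
  expect_equal(ii$value, 1, tolerance = 1e-6)
  expect_error(dtauWLogDensity(0, 1.2, 0.97, 0), "sigmaC")
})

test_that("psiBeta collapses to a plain normal when z = 1", {
  for (d in c(-1, 0.4, 3)) {
    expect_equal(psiBeta(d, m = 2, n = 4, k = 1, deltaT = 1.2, z = 1,
                         eta = 0.97, sigmaC = 0.2),
                 dnorm(d, -log(1.2) / log(1.97), sqrt(2) * 0.2),
                 tolerance = 1e-8)
  }
})

test_that("psiBeta matches a Monte-Carlo average over the beta ratio", {
  set.seed(202)
  B <- 1e6L
  y <- rbeta(B, 2, 2)   # m = 2, n = 4, k = 1
  for (d in c(0.5, 2, 5)) {
    v <- dnorm(d, -(log(1.2) + log(0.0016 + (1 - 0.0016) * y)) / log(1.97),
               sqrt(2) * 0.2)
    est <- mean(v); se <- sd(v) / sqrt(B)
    expect_lt(abs(psiBeta(d, 2, 4, 1, 1.2, 0.0016, 0.97, 0.2) - est), 3 * se)
  }
})

test_that("psiBeta is a density in dtauD (integrates to one)", {
  for (k in c(0.6, 1, 5)) {
    ii <- integrate(Vectorize(function(d)
      psiBeta(d, m = 1, n = 3, k = k, deltaT = 1.2, z = 0.0016,
              eta = 0.97, sigmaC = 0.2)), -5, 15)
    expect_equal(ii$value, 1, tolerance = 1e-5)
  }
})

test_that("psiGamma equals psiBeta and is scale-invariant", {
  for (d in c(-0.5, 1.5, 6)) for (k in c(0.7, 3)) {
    pb <- psiBeta(d, 1, 2, k, 1.2, 0.0016, 0.97, 0.2)
    pg <- psiGamma(d, 1, 2, k, 1.2, 0.0016, 0.97, 0.2)
    expect_equal(pg, pb, tolerance = 1e-7)
    expect_equal(psiGamma(d, 1, 2, k, 1.2, 0.0016, 0.97, 0.2, theta = 1e3),
                 pg, tolerance = 1e-9)
  }
})

test_that("psiGamma matches Monte Carlo over exponential draws", {
  set.seed(303)
  B <- 1e6L
  r <- rexp(B); s <- rexp(B)   # m = 1, n = 2, k = 1, theta = 1
  w <- (r + 0.0016 * s) / (r + s)
  for (d in c(1, 4)) {
    v <- dnorm(d, -(log(1.2) + log(w)) / log(1.97), sqrt(2) * 0.2)
    est <- mean(v); se <- sd(v) / sqrt(B)
    expect_lt(abs(psiGamma(d, 1, 2, 1, 1.2, 0.0016, 0.97, 0.2) - est), 3 * se)
  }
})

test_that("degenerate m is rejected by the interior kernels", {
  expect_error(psiBeta(1, 0, 4, 1, 1.2, 0.0016, 0.97, 0.2), "m")
  expect_error(psiBeta(1, 4, 4, 1, 1.2, 0.0016, 0.97, 0.2), "m")
  expect_error(psiGamma(1, 0, 4, 1, 1.2, 0.0016, 0.97, 0.2), "m")
})

test_that("bulk log-likelihood reduces to the degenerate branches at p = 0, 1", {
  L <- log(1.97); sdv <- sqrt(2) * 0.2
  for (d in c(0.3, 7)) for (n in c(1L, 4L)) {
    ll0 <- dtauWLogDensity(0.1, 1.2, 0.97, 0.2) +
      dnorm(d, -(log(0.0016) + log(1.2)) / L, sdv, log = TRUE)
    expect_equal(bulkLoglik(0.1, d, n, p = 0, k = 1, deltaT = 1.2,
                            sigmaC = 0.2, z = 0.0016, eta = 0.97), ll0,
                 tolerance = 1e-10)
    lln <- dtauWLogDensity(0.1, 1.2, 0.97, 0.2) +
      dnorm(d, -log(1.2) / L, sdv, log = TRUE)
    expect_equal(bulkLoglik(0.1, d, n, p = 1, k = 1, deltaT = 1.2,
                            sigmaC = 0.2, z = 0.0016, eta = 0.97), lln,
                 tolerance = 1e-10)
  }
})

test_that("bulk log-likelihood equals the explicit mixture sum for n = 2", {
  L <- log(1.97); sdv <- sqrt(2) * 0.2
  p <- 0.3; k <- 1.4; dT <- 1.2; z <- 0.0016; s <- 0.2
  for (d in c(0.2, 3, 8)) {
    manual <- dbinom(0, 2, p) * dnorm(d, -(log(z) + log(dT)) / L, sdv) +
      dbinom(1, 2, p) * psiBeta(d, 1, 2, k, dT, z, 0.97, s) +
      dbinom(2, 2, p) * dnorm(d, -log(dT) / L, sdv)
    ref <- dtauWLogDensity(-0.4, dT, 0.97, s) + log(manual)
    expect_equal(bulkLoglik(-0.4, d, 2, p, k, dT, s, z, 0.97,
                            engine = "adaptive"), ref, tolerance = 1e-9)
    expect_equal(bulkLoglik(-0.4, d, 2, p, k, dT, s, z, 0.97,
                            engine = "quadrature"), ref, tolerance = 1e-5)
  }
})

test_that("fast quadrature and adaptive engines agree across pool sizes", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(c(2L, 5L, 16L, 48L), 1)
    d <- runif(1, -1, 10); p <- runif(1, 0.02, 0.95); k <- runif(1, 0.4, 10)
    a <- bulkLoglik(0.1, d, n, p, k, 1.2, 0.2, 0.0016, 0.97,
                    engine = "quadrature")
    b <- bulkLoglik(0.1, d, n, p, k, 1.2, 0.2, 0.0016, 0.97,
                    engine = "adaptive")
    expect_equal(a, b, tolerance = 1e-4)
  }
})

test_that("total negative log-likelihood is additive and order-invariant", {
  d <- smallBulk()
  dd <- deltaCq(d); dd$n <- poolSize(d)
  base <- totalNegLoglik(dd, p = .25, k = 1, deltaT = 1.2, sigmaC = .2,
                         z = 0.0016, eta = 0.97)
  expect_equal(totalNegLoglik(rbind(dd, dd), .25, 1, 1.2, .2, 0.0016, 0.97),
               2 * base)
  perm <- dd[c(3, 1, 2), ]
  expect_equal(totalNegLoglik(perm, .25, 1, 1.2, .2, 0.0016, 0.97), base)
  ## equals the sum of single-sample likelihoods
  single <- sum(vapply(seq_len(nrow(dd)), function(i)
    bulkLoglik(dd$dtauW[i], dd$dtauD[i], dd$n[i], .25, 1, 1.2, .2,
               0.0016, 0.97), numeric(1)))
  expect_equal(base, -single)
  expect_error(totalNegLoglik(dd[1, ], .25, 1, 1.2, .2, 0.0016, 0.97),
               "at least two")
})

test_that("the objective is smooth in the transformed parameters", {
  d <- smallBulk(N = 4L, n = 8L, p = 0.2, seed = 55L)
  dd <- deltaCq(d); dd$n <- poolSize(d)
  f <- function(tv)
    totalNegLoglik(dd, plogis(tv[1]), exp(tv[2]), exp(tv[3]), exp(tv[4]),
                   z = 0.0016, eta = 0.97)
  x0 <- c(qlogis(0.2), 0, log(1.2), log(0.2))
  h <- 1e-5
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    d1 <- (f(x0 + e) - f(x0 - e)) / (2 * h)
    d2 <- (f(x0 + 2 * e) - f(x0 - 2 * e)) / (4 * h)
    expect_true(is.finite(d1))
    expect_equal(d1, d2, tolerance = 1e-3)
  }
})
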