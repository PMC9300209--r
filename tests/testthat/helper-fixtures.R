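## Shared fixtures: assay parameter sets and small simulated datasets.

## Defaults of the numerical experiments.
simParams <- function(...) QpcrParams(...)

## The calibrated mite-assay values used as a realistic parameter point.
miteParams <- function() {
  QpcrParams(eta = 0.9712, deltaT = 1.170, deltaB = 0.2361, z = 0.001564,
             sigmaC = 0.2376, meanDNA = 1.256e-6)
}

## A small deterministic bulk dataset for likelihood plumbing tests.
smallBulk <- function(N = 3L, n = 4L, p = 0.25, seed = 101L) {
  simulateBulkCq(SimDesign(p = p, k = 1, nPerSample = n, nSamples = N),
                 seed = seed)
}

## Monte-Carlo estimate of the binomial-mixture density of dtauD, the
## independent oracle for the likelihood (draws the latent state directly).
mcMixtureDensity <- function(dtauD, n, p, k, deltaT, sigmaC, z, eta,
                             B = 1e6L) {
  L <- log(1 + eta)
  m <- rbinom(B, n, p)
  w <- numeric(B)
  w[m == 0L] <- z
  w[m == n] <- 1
  mid <- which(m > 0L & m < n)
  if (length(mid)) {
    y <- rbeta(length(mid), m[mid] * k, (n - m[mid]) * k)
    w[mid] <- z + (1 - z) * y
  }
  v <- dnorm(dtauD, -(log(deltaT) + log(w)) / L, sqrt(2) * sigmaC)
  c(est = mean(v), se = sd(v) / sqrt(B))
}
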