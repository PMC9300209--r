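## Marginal likelihood of one bulk sample's (dtauW, dtauD) pair: a binomial
## mixture over the latent number m of R individuals, with the interior terms
## marginalized over the latent sample allele ratio (beta kernel) or the two
## latent allelic DNA amounts (gamma kernel).

#' Log-density of the control-condition Delta-Cq
#'
#' Under the Cq error model, \eqn{\Delta\tau_W \sim
#' N(-\ln\delta_T/\ln(1+\eta),\, 2\sigma_c^2)}: the control Delta-Cq carries
#' information on \eqn{\delta_T} only, not on the allele ratio.
#'
#' @param dtauW observed control Delta-Cq (vectorized).
#' @param deltaT target-to-housekeeping content ratio (> 0).
#' @param eta amplification efficiency (> 0).
#' @param sigmaC Cq measurement error SD (> 0).
#' @return log-density values.
#' @examples
#' dtauWLogDensity(0, deltaT = 1, eta = 0.97, sigmaC = 0.2)
#' @export
dtauWLogDensity <- function(dtauW, deltaT, eta, sigmaC) {
  .assertScalarPositive(deltaT, "deltaT")
  .assertScalarPositive(eta, "eta")
  .assertScalarPositive(sigmaC, "sigmaC")
  dnorm(dtauW, mean = -log(deltaT) / log(1 + eta), sd = sqrt(2) * sigmaC,
        log = TRUE)
}

## Candidate integration breakpoints: the allele-ratio values w = z + y(1-z)
## at which the normal kernel for dtauD is centred +/- a few SD.
.ratioWindow <- function(dtauD, deltaT, L, sdv, z) {
  w <- exp(-L * dtauD - log(deltaT) + L * sdv * c(-8, -4, -1, 0, 1, 4, 8))
  y <- (w - z) / (1 - z)
  y[which(y > 0 & y < 1)]
}

#' Beta-kernel marginal density of the test-condition Delta-Cq
#'
#' For a bulk sample with \eqn{1 \le m \le n-1} R individuals, the latent
#' sample ratio is \eqn{y \sim \mathrm{Beta}(mk, (n-m)k)} and
#' \deqn{\psi_B = \int_0^1 N\!\left(\Delta\tau_D;\,
#'   -\tfrac{\ln\delta_T + \ln\{z + y(1-z)\}}{\ln(1+\eta)},\, 2\sigma_c^2\right)
#'   \mathrm{Beta}(y \mid mk, (n-m)k)\, dy.}
#' Computed by adaptive quadrature after the substitution \eqn{y = F^{-1}(u)}
#' (the beta quantile function), which absorbs the beta density and its
#' endpoint singularities; the integration range is split where the normal
#' kernel is centred so that narrow features are resolved.
#'
#' @param dtauD observed test-condition Delta-Cq (scalar).
#' @param m number of R individuals, \code{1 <= m <= n-1}.
#' @param n pool size.
#' @param k gamma shape of the individual DNA yield.
#' @param deltaT,z,eta,sigmaC assay parameters (all > 0).
#' @param relTol relative tolerance of the quadrature.
#' @return the marginal density (a density in \code{dtauD}).
#' @examples
#' psiBeta(2, m = 2, n = 4, k = 1, deltaT = 1.2, z = 0.0016,
#'         eta = 0.97, sigmaC = 0.2)
#' @export
psiBeta <- function(dtauD, m, n, k, deltaT, z, eta, sigmaC, relTol = 1e-10) {
  stopifnot(length(dtauD) == 1L, is.finite(dtauD))
  if (m < 1 || m > n - 1 || m != round(m))
    stop("'m' must be an integer with 1 <= m <= n - 1 (the degenerate m = 0 ",
         "and m = n cases are plain normal densities, not beta mixtures)",
         call. = FALSE)
  for (nm in c("k", "deltaT", "z", "eta", "sigmaC"))
    .assertScalarPositive(get(nm), nm)
  L <- log(1 + eta)
  sdv <- sqrt(2) * sigmaC
  a <- m * k
  b <- (n - m) * k
  phi <- function(lw) dnorm(dtauD, -(log(deltaT) + lw) / L, sdv)
  ## The integral is evaluated in log coordinates (log y below 1/2, log(1-y)
  ## above), where both the beta endpoint behaviour and the normal kernel --
  ## whose log-ratio mean varies on a relative y scale -- stay resolvable
  ## arbitrarily deep in the tails. Below yLo the ratio is within 0.1% of its
  ## floor z and above yHi within 1e-4 of 1; those slivers enter as atoms
  ## with the limiting means.
  yLo <- z * 1e-6
  yHi <- 1 - 1e-7
  ys <- .ratioWindow(dtauD, deltaT, L, sdv, z)   # normal-kernel centres
  f1 <- function(t) {
    y <- exp(t)
    phi(log(z + (1 - z) * y)) * dbeta(y, a, b) * y
  }
  f2 <- function(s) {
    u <- exp(s)
    phi(log(z + (1 - z) * (1 - u))) * dbeta(1 - u, a, b) * u
  }
  seg1 <- sort(unique(c(log(yLo), log(ys[ys > yLo & ys < 0.5]), log(0.5))))
  yhi2 <- ys[ys >= 0.5 & ys < yHi]
  seg2 <- sort(unique(c(log(1 - yHi), log(1 - yhi2), log(0.5))))
  tot <- pbeta(yLo, a, b) * phi(log(z)) +
    pbeta(yHi, a, b, lower.tail = FALSE) * phi(0)
  for (i in seq_len(length(seg1) - 1L))
    tot <- tot + integrate(f1, seg1[i], seg1[i + 1L], rel.tol = relTol,
                           abs.tol = 0, subdivisions = 400L,
                           stop.on.error = FALSE)$value
  for (i in seq_len(length(seg2) - 1L))
    tot <- tot + integrate(f2, seg2[i], seg2[i + 1L], rel.tol = relTol,
                           abs.tol = 0, subdivisions = 400L,
                           stop.on.error = FALSE)$value
  max(tot, 0)   # guard against extrapolation noise of deep-tail segments
}

#' Gamma-kernel marginal density of the test-condition Delta-Cq
#'
#' The same marginal as \code{\link{psiBeta}}, computed by double integration
#' over the latent allelic DNA amounts \eqn{r \sim \mathrm{Ga}(mk, \theta)}
#' and \eqn{s \sim \mathrm{Ga}((n-m)k, \theta)}, with the allele ratio
#' entering as \eqn{(r + zs)/(r + s)}. The integral is evaluated on the unit
#' square via the gamma quantile transform, which makes the \eqn{\theta}
#' invariance exact (the scale cancels in the ratio) and removes the endpoint
#' singularities. Exists mainly as an independent cross-check of the beta
#' kernel (the two are mathematically identical) and as the compatibility
#' path for gamma-kernel fitting.
#'
#' @inheritParams psiBeta
#' @param theta gamma scale parameter; the result is invariant to it.
#' @param relTol relative tolerance of the outer quadrature.
#' @return the marginal density.
#' @examples
#' psiGamma(2, m = 2, n = 4, k = 1, deltaT = 1.2, z = 0.0016,
#'          eta = 0.97, sigmaC = 0.2)
#' @export
psiGamma <- function(dtauD, m, n, k, deltaT, z, eta, sigmaC, theta = 1,
                     relTol = 1e-9) {
  stopifnot(length(dtauD) == 1L, is.finite(dtauD))
  if (m < 1 || m > n - 1 || m != round(m))
    stop("'m' must be an integer with 1 <= m <= n - 1", call. = FALSE)
  for (nm in c("k", "deltaT", "z", "eta", "sigmaC", "theta"))
    .assertScalarPositive(get(nm), nm)
  L <- log(1 + eta)
  sdv <- sqrt(2) * sigmaC
  a <- m * k
  b <- (n - m) * k
  phi <- function(lw) dnorm(dtauD, -(log(deltaT) + lw) / L, sdv)
  ## centred-ratio values for inner breakpoints
  wc <- exp(-L * dtauD - log(deltaT) + L * sdv * c(-8, -4, -1, 0, 1, 4, 8))
  wc <- wc[wc > z & wc < 1]
  ## inner integral over the R amount r, in log r coordinates so that the
  ## normal-kernel feature (located at r* proportional to s) is resolvable
  ## however little gamma mass it carries; r below z*s*1e-3 leaves the ratio
  ## within 0.1% of z and r above 1e4*s within 1e-4 of 1 (endpoint atoms)
  innerOne <- function(s) {
    if (!is.finite(s) || s <= 0)    # degenerate outer node: ratio is 1
      return(phi(0))
    rLo <- z * s * 1e-6
    rHi <- s * 1e7
    f <- function(t) {
      r <- exp(t)
      phi(log((r + z * s) / (r + s))) * dgamma(r / theta, a) * r / theta
    }
    anchors <- c(s * (wc - z) / (1 - wc),              # kernel centres
                 theta * qgamma(c(0.01, 0.5, 0.99), a)) # gamma bulk
    segs <- sort(unique(c(log(rLo),
                          log(anchors[anchors > rLo & anchors < rHi]),
                          log(rHi))))
    tot <- pgamma(rLo / theta, a) * phi(log(z)) +
      pgamma(rHi / theta, a, lower.tail = FALSE) * phi(0)
    for (i in seq_len(length(segs) - 1L))
      tot <- tot + integrate(f, segs[i], segs[i + 1L], rel.tol = relTol / 10,
                             abs.tol = 0, subdivisions = 400L,
                             stop.on.error = FALSE)$value
    max(tot, 0)
  }
  ## outer integral over the S amount, also in log coordinates: the joint
  ## (r, s) saddle of a tail feature sits at s* = theta (a + b - 2)/(1 + c)
  ## with c = (w* - z)/(1 - w*), which may carry arbitrarily little gamma
  ## mass; anchoring segments there keeps it resolvable. In the s -> 0 limit
  ## the ratio is 1 and in the s -> infinity limit it is z (endpoint atoms).
  cs <- (wc - z) / (1 - wc)
  sStar <- if (a + b > 2) theta * (a + b - 2) / (1 + cs) else numeric(0)
  sLo <- theta * qgamma(1e-13, b)
  sHi <- theta * qgamma(1e-13, b, lower.tail = FALSE)
  if (length(sStar)) {
    sLo <- min(sLo, min(sStar) / 50)
    sHi <- max(sHi, max(sStar) * 50)
  }
  sLo <- max(sLo, 1e-290)
  g <- function(t) {
    s <- exp(t)
    vapply(s, innerOne, numeric(1L)) * dgamma(s / theta, b) * s / theta
  }
  anchors <- c(sStar, theta * qgamma(c(0.01, 0.5, 0.99), b))
  segs <- sort(unique(c(log(sLo), log(anchors[anchors > sLo & anchors < sHi]),
                        log(sHi))))
  tot <- pgamma(sLo / theta, b) * phi(0) +
    pgamma(sHi / theta, b, lower.tail = FALSE) * phi(log(z))
  for (i in seq_len(length(segs) - 1L))
    tot <- tot + integrate(g, segs[i], segs[i + 1L], rel.tol = relTol,
                           abs.tol = 0, subdivisions = 200L,
                           stop.on.error = FALSE)$value
  max(tot, 0)
}

## ---------------------------------------------------------------------------
## Fast fixed-rule quadrature for the beta kernel (used by the fitting path)
## ---------------------------------------------------------------------------

## Composite Gauss-Legendre grid for E_y[phi(y)], y ~ Beta(a, b), built on
## log(y) panels below 1/2 and log(1-y) panels above, with panel edges
## augmented by beta quantiles so that both a concentrated beta mass and the
## narrow normal kernel (whose log-ratio mean varies on a relative y scale)
## are resolved. The region y < z*1e-3 (ratio within 0.1% of its floor z) and
## y > 1 - 1e-4 are handled as endpoint atoms with the limiting means.
## Returns node positions y and the k-independent part of the log-weights
## (GL weight x panel width x jacobian of the log coordinate); the beta
## density itself is factored in at evaluation time so that one cached grid
## serves nearby k values exactly.
.betaPanelNodes <- function(a, b, z, nGL = 8L) {
  yLo <- z * 1e-3
  yHi <- 1 - 1e-4
  gl <- .gaussLegendre01(nGL)
  lo <- exp(seq(log(yLo), log(0.5), length.out =
                  max(2L, ceiling((log(0.5) - log(yLo)) / log(10)) + 1L)))
  hi <- 1 - exp(seq(log(0.5), log(1 - yHi), length.out =
                      max(2L, ceiling((log(0.5) - log(1 - yHi)) / log(10)) + 1L)))
  qs <- qbeta(c(1e-6, 1e-3, .01, .05, .15, .3, .5, .7, .85, .95, .99,
                .999, 1 - 1e-6), a, b)
  edges <- sort(unique(c(lo, hi, 0.5, qs[qs > yLo & qs < yHi])))
  edges <- edges[c(TRUE, diff(log(edges)) > 1e-6)]
  np <- length(edges) - 1L
  y1 <- edges[-length(edges)]; y2 <- edges[-1L]
  low <- y2 <= 0.5 + 1e-12
  ## node positions and log(GL weight x width) + log-jacobian, per panel
  t1 <- ifelse(low, log(y1), log(1 - y2))
  t2 <- ifelse(low, log(y2), log(1 - y1))
  tj <- rep(t1, each = nGL) + rep(t2 - t1, each = nGL) * gl$x
  yj <- ifelse(rep(low, each = nGL), exp(tj), 1 - exp(tj))
  base <- log(gl$w) + rep(log(t2 - t1), each = nGL) + tj
  list(y = yj, base = base)
}

## Full mixture grid for one pool size nn: nodes of every interior m plus the
## four kinds of atoms (m = 0, m = n, and the per-m endpoint lumps). Geometry
## is cached on a lightly quantized k (signif 3); the k- and p-dependent
## weights are recomputed exactly at every likelihood evaluation.
.betaGrid <- function(cache, nn, k, z, nGL = 8L) {
  kq <- signif(k, 3L)
  key <- sprintf("B|%d|%.17g|%.17g|%d", nn, kq, z, nGL)
  g <- cache[[key]]
  if (!is.null(g)) return(g)
  ys <- bases <- midx <- vector("list", max(nn - 1L, 0L))
  for (m in seq_len(nn - 1L)) {
    nd <- .betaPanelNodes(m * kq, (nn - m) * kq, z, nGL = nGL)
    ys[[m]] <- nd$y
    bases[[m]] <- nd$base
    midx[[m]] <- rep.int(m, length(nd$y))
  }
  y <- unlist(ys, use.names = FALSE)
  g <- list(y = y,
            base = unlist(bases, use.names = FALSE),
            mIdx = unlist(midx, use.names = FALSE),
            lw = log(z + (1 - z) * y),
            yLo = z * 1e-3, yHi = 1 - 1e-4)
  cache[[key]] <- g
  g
}

## Log of the full binomial-mixture density of dtauD for all samples of pool
## size nn (beta kernel, fixed-rule path): a single weighted log-sum-exp over
## interior quadrature nodes and degenerate atoms, with the binomial weights
## folded into the node weights.
.betaMixtureLogDens <- function(dtauD, nn, p, k, deltaT, sigmaC, z, L, cache,
                                nGL = 8L) {
  logb <- dbinom(0:nn, nn, p, log = TRUE)
  v <- 2 * sigmaC^2
  lc <- -0.5 * log(2 * pi * v)
  if (nn >= 2L) {
    g <- .betaGrid(cache, nn, k, z, nGL = nGL)
    a <- g$mIdx * k
    b <- (nn - g$mIdx) * k
    logW <- g$base + dbeta(g$y, a, b, log = TRUE) + logb[g$mIdx + 1L]
    mi <- seq_len(nn - 1L)
    lumpLo <- pbeta(g$yLo, mi * k, (nn - mi) * k, log.p = TRUE) + logb[mi + 1L]
    lumpHi <- pbeta(g$yHi, mi * k, (nn - mi) * k, lower.tail = FALSE,
                    log.p = TRUE) + logb[mi + 1L]
    lw <- c(g$lw, rep.int(log(z), nn - 1L), rep.int(0, nn - 1L), log(z), 0)
    w <- c(logW, lumpLo, lumpHi, logb[1L], logb[nn + 1L])
  } else {
    lw <- c(log(z), 0)
    w <- logb
  }
  keep <- which(w > -Inf)
  lw <- lw[keep]; w <- w[keep]
  mu <- -(log(deltaT) + lw) / L
  lphi <- lc - (outer(dtauD, mu, "-"))^2 / (2 * v)
  .rowLogSumExp(lphi + rep(w, each = length(dtauD)))
}

## Tensor-product nodes for the gamma kernel: gamma quantile transform on the
## unit square. Coarser than the beta path; the gamma kernel is the slower
## compatibility/cross-check route.
.gammaQuadNodes <- function(a, b, z, nGL = 24L) {
  gl <- .gaussLegendre01(nGL)
  r <- qgamma(gl$x, a)
  s <- qgamma(gl$x, b)
  ratio <- outer(r, s, function(ri, sj) (ri + z * sj) / (ri + sj))
  list(lw = as.vector(log(ratio)),
       logW = as.vector(outer(log(gl$w), log(gl$w), "+")))
}

.nodeCache <- function() new.env(parent = emptyenv())

.getGammaNodes <- function(cache, n, m, k, z) {
  key <- sprintf("G|%d|%d|%.17g|%.17g", n, m, k, z)
  nd <- cache[[key]]
  if (is.null(nd)) {
    nd <- .gammaQuadNodes(m * k, (n - m) * k, z)
    cache[[key]] <- nd
  }
  nd
}

## Per-sample log-likelihood vector; the workhorse shared by bulkLoglik,
## totalNegLoglik and the estimateFreq objective.
.logLikSamples <- function(dtauW, dtauD, n, p, k, deltaT, sigmaC, z, eta,
                           kernel = "beta", engine = "quadrature",
                           theta = 1, cache = NULL, nGL = 8L) {
  L <- log(1 + eta)
  sdv <- sqrt(2) * sigmaC
  v <- sdv^2
  lc <- -0.5 * log(2 * pi * v)
  if (is.null(cache)) cache <- .nodeCache()
  llW <- dnorm(dtauW, -log(deltaT) / L, sdv, log = TRUE)
  lp0 <- dnorm(dtauD, -(log(z) + log(deltaT)) / L, sdv, log = TRUE)
  lpn <- dnorm(dtauD, -log(deltaT) / L, sdv, log = TRUE)
  out <- numeric(length(dtauD))
  for (nn in unique(n)) {
    idx <- which(n == nn)
    if (kernel == "beta" && engine == "quadrature") {
      out[idx] <- llW[idx] +
        .betaMixtureLogDens(dtauD[idx], nn, p, k, deltaT, sigmaC, z, L, cache,
                            nGL = nGL)
      next
    }
    logb <- dbinom(0:nn, nn, p, log = TRUE)
    terms <- matrix(-Inf, length(idx), nn + 1L)
    terms[, 1L] <- logb[1L] + lp0[idx]
    terms[, nn + 1L] <- logb[nn + 1L] + lpn[idx]
    if (nn >= 2L) {
      for (m in seq_len(nn - 1L)) {
        if (!is.finite(logb[m + 1L])) next   # impossible m under p = 0 or 1
        if (engine == "quadrature") {        # gamma kernel, fixed tensor rule
          nd <- .getGammaNodes(cache, nn, m, k, z)
          mu <- -(log(deltaT) + nd$lw) / L
          lphi <- lc - (outer(dtauD[idx], mu, "-"))^2 / (2 * v)
          lphi <- lphi + matrix(nd$logW, nrow = length(idx),
                                ncol = length(mu), byrow = TRUE)
          terms[, m + 1L] <- logb[m + 1L] + .rowLogSumExp(lphi)
        } else {
          psi <- vapply(dtauD[idx], function(d)
            if (kernel == "beta")
              psiBeta(d, m, nn, k, deltaT, z, eta, sigmaC)
            else
              psiGamma(d, m, nn, k, deltaT, z, eta, sigmaC, theta = theta),
            numeric(1L))
          terms[, m + 1L] <- logb[m + 1L] + log(psi)
        }
      }
    }
    out[idx] <- llW[idx] + .rowLogSumExp(terms)
  }
  out
}

#' Log-likelihood of one bulk sample's Delta-Cq pair
#'
#' Evaluates \deqn{\log L_h = \log P(\Delta\tau_W) + \log \sum_{m=0}^{n}
#' \mathrm{Bin}(m \mid n, p)\, P(\Delta\tau_D \mid m)} where the \eqn{m = 0}
#' and \eqn{m = n} branches are plain normal densities (means
#' \eqn{-\ln(z\delta_T)/\ln(1+\eta)} and \eqn{-\ln\delta_T/\ln(1+\eta)}) and
#' the interior branches use \code{\link{psiBeta}} or \code{\link{psiGamma}}.
#' The mixture is accumulated in log space.
#'
#' @param dtauW,dtauD the sample's two Delta-Cq observables.
#' @param n pool size (>= 1).
#' @param p population R frequency in [0, 1] (the endpoints are supported as
#'   limits).
#' @param k,deltaT,sigmaC,z,eta model parameters (> 0).
#' @param kernel \code{"beta"} (default) or \code{"gamma"}.
#' @param engine \code{"quadrature"} (fast fixed-rule path used in fitting) or
#'   \code{"adaptive"} (adaptive quadrature via \code{psiBeta}/\code{psiGamma}).
#' @param theta gamma scale (gamma kernel only; no effect on the value).
#' @return the log-likelihood (scalar).
#' @examples
#' bulkLoglik(0.2, 4.1, n = 4, p = 0.3, k = 1, deltaT = 1.2,
#'            sigmaC = 0.2, z = 0.0016, eta = 0.97)
#' @export
bulkLoglik <- function(dtauW, dtauD, n, p, k, deltaT, sigmaC, z, eta,
                       kernel = c("beta", "gamma"),
                       engine = c("quadrature", "adaptive"), theta = 1) {
  kernel <- match.arg(kernel)
  engine <- match.arg(engine)
  stopifnot(length(dtauW) == 1L, length(dtauD) == 1L, n >= 1L)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]", call. = FALSE)
  for (nm in c("k", "deltaT", "sigmaC", "z", "eta"))
    .assertScalarPositive(get(nm), nm)
  .logLikSamples(dtauW, dtauD, as.integer(n), p, k, deltaT, sigmaC, z, eta,
                 kernel = kernel, engine = engine, theta = theta)
}

#' Total negative log-likelihood over N bulk samples
#'
#' The objective minimized by \code{\link{estimateFreq}}:
#' \eqn{-\sum_h \log L_h}. At least two bulk samples are required: with a
#' single sample the data are two Delta-Cq values against up to four free
#' parameters and the model is not estimable.
#'
#' @param data a \linkS4class{BulkCqData}, or a data.frame with columns
#'   \code{dtauW}, \code{dtauD}, \code{n}.
#' @inheritParams bulkLoglik
#' @return scalar negative log-likelihood.
#' @examples
#' d <- simulateBulkCq(SimDesign(p = .25, k = 1, nPerSample = 4,
#'                               nSamples = 4), seed = 1)
#' totalNegLoglik(d, p = .25, k = 1, deltaT = 1.2, sigmaC = 0.2,
#'                z = 0.0016, eta = 0.97)
#' @export
totalNegLoglik <- function(data, p, k, deltaT, sigmaC, z, eta,
                           kernel = c("beta", "gamma"),
                           engine = c("quadrature", "adaptive"), theta = 1) {
  kernel <- match.arg(kernel)
  engine <- match.arg(engine)
  if (is(data, "BulkCqData")) {
    dd <- deltaCq(data)
    dd$n <- poolSize(data)
  } else {
    dd <- as.data.frame(data)
    if (!all(c("dtauW", "dtauD", "n") %in% names(dd)))
      stop("'data' must be BulkCqData or have columns dtauW, dtauD, n",
           call. = FALSE)
  }
  if (nrow(dd) < 2L)
    stop("at least two bulk samples are required: a single sample provides ",
         "two Delta-Cq observables against up to four free parameters",
         call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]", call. = FALSE)
  for (nm in c("k", "deltaT", "sigmaC", "z", "eta"))
    .assertScalarPositive(get(nm), nm)
  -sum(.logLikSamples(dd$dtauW, dd$dtauD, as.integer(dd$n), p, k, deltaT,
                      sigmaC, z, eta, kernel = kernel, engine = engine,
                      theta = theta))
}
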