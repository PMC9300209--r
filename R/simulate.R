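## Synthetic-data generation: dummy Cq datasets under the full generative
## model, plus the grid harness that sweeps parameter regions and summarizes
## estimation success and precision.

#' Simulate bulk-sample Cq quartets
#'
#' Draws one dataset under the generative model of a haploid population with
#' R frequency \code{p}: for each of \code{N} bulk samples,
#' \eqn{m_h \sim \mathrm{Bin}(n, p)} R individuals, allelic DNA amounts
#' \eqn{X_R \sim \mathrm{Ga}(m_h k, \theta)} and
#' \eqn{X_S \sim \mathrm{Ga}((n - m_h)k, \theta)} with
#' \eqn{\theta = \mathrm{meanYield}/k} (a gamma draw with shape 0 is exactly
#' 0), and the four Cq values as the noise-free expectation
#' (\code{\link{expectedCq}}) plus four independent
#' \eqn{N(0, \sigma_c^2)} errors -- so the \eqn{4\sigma_c^2} variance of
#' \eqn{\Delta\Delta\tau} emerges from the model rather than being injected.
#' The latent pool state is retained in \code{latentState()} for oracle
#' checks.
#'
#' @param design a \linkS4class{SimDesign}.
#' @param seed optional integer seed (set via \code{set.seed}).
#' @return A \linkS4class{BulkCqData} whose metadata holds the latent
#'   data.frame (\code{m}, \code{xR}, \code{xS}, \code{yR}).
#' @examples
#' d <- simulateBulkCq(SimDesign(p = 0.1, k = 1, nPerSample = 8,
#'                               nSamples = 4), seed = 1)
#' latentState(d)
#' @export
simulateBulkCq <- function(design, seed = NULL) {
  stopifnot(is(design, "SimDesign"))
  if (!is.null(seed)) set.seed(seed)
  N <- design@nSamples
  n <- design@nPerSample
  theta <- design@meanYield / design@k
  m <- rbinom(N, n, design@p)
  xR <- ifelse(m > 0L,
               rgamma(N, shape = m * design@k, scale = theta), 0)
  xS <- ifelse(m < n,
               rgamma(N, shape = (n - m) * design@k, scale = theta), 0)
  pars <- design@params
  mu <- expectedCq(pars, xR, xS)
  cq <- as.matrix(mu) + matrix(rnorm(4L * N, 0, pars@sigmaC), N, 4L)
  colnames(cq) <- .cqCols
  BulkCqData(housek0 = cq[, 1L], target0 = cq[, 2L], housek1 = cq[, 3L],
             target1 = cq[, 4L], n = n,
             metadata = list(
               latent = data.frame(m = m, xR = xR, xS = xS,
                                   yR = xR / (xR + xS)),
               design = design, seed = seed))
}

#' Simulate known-ratio calibration Cq data
#'
#' Generates a calibration dataset at given mixing ratios under the
#' deterministic known-ratio means (\code{\link{knownCqMean}}) plus
#' independent \eqn{N(0, \sigma_c^2)} Cq noise. By default it emulates the
#' layout of a RED-\eqn{\Delta\Delta}Cq validation series: both genes in the
#' digested condition at every ratio, but the undigested condition only where
#' \code{undigestedRatios} says so (the classical design measures it only on
#' the pure-R solution, ratio 1).
#'
#' @param params a \linkS4class{QpcrParams}; \code{meanDNA} is the total
#'   template of each solution, \code{sigmaC} the Cq noise.
#' @param ratio vector of mixing ratios.
#' @param replicates number of replicates per ratio.
#' @param undigestedRatios ratios at which the undigested (condition 0)
#'   channels are measured; default \code{1}. Use \code{ratio} for a complete
#'   (paired) design.
#' @param seed optional integer seed.
#' @return A \linkS4class{KnownRatioData}.
#' @export
simulateKnownRatio <- function(params,
                               ratio = c(0, 0.001, 0.005, 0.01, 0.05, 0.1,
                                         0.25, 0.5, 0.75, 1),
                               replicates = 4L, undigestedRatios = 1,
                               seed = NULL) {
  stopifnot(is(params, "QpcrParams"))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(ratio = ratio, gene = c("housek", "target"),
                      condition = c(0L, 1L),
                      replicate = sprintf("rep%d", seq_len(replicates)),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$condition == 1L | grid$ratio %in% undigestedRatios, ]
  mu <- knownCqMean(params, grid$ratio, grid$gene, grid$condition)
  KnownRatioData(ratio = grid$ratio, gene = grid$gene,
                 condition = grid$condition, replicate = grid$replicate,
                 cq = mu + rnorm(nrow(grid), 0, params@sigmaC))
}

#' Rule-of-three sample-size threshold
#'
#' The total sample size above which a population with allele frequency
#' \code{p} is expected to contribute at least one carrier with about 95%
#' probability: \code{3 / p}. Grid summaries flag parameter regions by the
#' strict comparison \eqn{Nn > 3/p}.
#'
#' @param p allele frequency, \code{0 < p <= 1}.
#' @return the threshold \code{3 / p}.
#' @examples
#' ruleOfThree(0.05)  # 60 individuals
#' @export
ruleOfThree <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("'p' must satisfy 0 < p <= 1", call. = FALSE)
  3 / p
}

#' Enumerate the parameter regions of the numerical experiment
#'
#' Builds the default grid: allele frequencies
#' \code{p in {0.01, 0.05, 0.1, 0.25, 0.5, 0.75}}, gamma shapes
#' \code{k in {1, 3, 9, 27}}, and all power-of-two sampling layouts with
#' \code{N in {2, ..., 64}} bulk samples of \code{n in {1, ..., 64}}
#' individuals and total size \code{4 <= Nn <= 128} (26 layouts), i.e. 624
#' regions in total.
#'
#' @param p,k,N,n candidate levels.
#' @param ntotalMin,ntotalMax bounds on the total sample size \code{N * n}.
#' @param params assay parameters shared by all regions.
#' @param meanYield mean individual DNA yield.
#' @return data.frame with one row per region (\code{region}, \code{p},
#'   \code{k}, \code{N}, \code{n}, \code{ntotal}, \code{ruleOfThree} flag).
#' @examples
#' nrow(gridDesigns())  # 624
#' @export
gridDesigns <- function(p = c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75),
                        k = c(1, 3, 9, 27),
                        N = 2^(1:6), n = 2^(0:6),
                        ntotalMin = 4L, ntotalMax = 128L,
                        params = QpcrParams(), meanYield = 1e-6) {
  g <- expand.grid(n = n, N = N, k = k, p = p)
  g <- g[g$N * g$n >= ntotalMin & g$N * g$n <= ntotalMax, ]
  g$ntotal <- g$N * g$n
  g$ruleOfThree <- g$ntotal > ruleOfThree(g$p)
  g <- g[order(g$p, g$k, g$ntotal, g$N), c("p", "k", "N", "n", "ntotal",
                                           "ruleOfThree")]
  g$region <- seq_len(nrow(g))
  rownames(g) <- NULL
  attr(g, "params") <- params
  attr(g, "meanYield") <- meanYield
  g
}

#' Run the simulation-estimation grid experiment
#'
#' For every region, simulates \code{replicates} independent datasets (one
#' RNG stream per (region, replicate) derived from the master seed by a fixed
#' counter scheme), fits the frequency model with
#' \code{\link{estimateFreq}} using the region's true \code{z} and \code{eta},
#' and also computes the conventional simple-averaging estimator with its
#' naive interval. Individual fit failures are recorded, never aborting the
#' grid.
#'
#' @param regions a data.frame from \code{\link{gridDesigns}} (or a subset of
#'   its rows).
#' @param replicates replicates per region.
#' @param seed master seed.
#' @param fixK \code{NULL} (estimate the gamma shape) or a fixed value.
#' @param kernel passed to \code{\link{estimateFreq}}.
#' @param level confidence level.
#' @return list of class \code{"gridResult"}: \code{$replicates}, one row per
#'   fit attempt (estimates, CI bounds, success flags, conventional
#'   estimator), and \code{$summary}, one row per region (success rate and
#'   25/50/75% quantiles of the estimate and of the CI bounds, the latter
#'   over successful replicates only, for both estimators).
#' @examples
#' g <- gridDesigns()[c(1, 100), ]
#' runGrid(g, replicates = 2, seed = 1, fixK = 1)$summary
#' @export
runGrid <- function(regions, replicates = 10L, seed = 1L, fixK = NULL,
                    kernel = "beta", level = 0.95) {
  params <- attr(regions, "params")
  if (is.null(params)) params <- QpcrParams()
  meanYield <- attr(regions, "meanYield")
  if (is.null(meanYield)) meanYield <- 1e-6
  rows <- vector("list", nrow(regions) * replicates)
  ri <- 0L
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    des <- SimDesign(p = reg$p, k = reg$k, nPerSample = reg$n,
                     nSamples = reg$N, params = params,
                     meanYield = meanYield)
    for (r in seq_len(replicates)) {
      ri <- ri + 1L
      dat <- simulateBulkCq(des, seed = .deriveSeed(seed, reg$region, r))
      dd <- deltaCq(dat)
      conv <- conventionalFreq(dd$ddtau, params@eta, level = level)
      fit <- tryCatch(
        estimateFreq(dat, z = params@z, eta = params@eta, kernel = kernel,
                     fixK = fixK, level = level),
        error = function(e) NULL)
      ok <- !is.null(fit)
      pOK <- ok && fitSuccess(fit, each = TRUE)[["p"]]
      rows[[ri]] <- data.frame(
        region = reg$region, p = reg$p, k = reg$k, N = reg$N, n = reg$n,
        ntotal = reg$ntotal, ruleOfThree = reg$ruleOfThree, replicate = r,
        fitted = ok,
        success = ok && fitSuccess(fit),
        pSuccess = pOK,
        pHat = if (ok) coef(fit)[["p"]] else NA_real_,
        pLower = if (pOK) confint(fit)["p", "lower"] else NA_real_,
        pUpper = if (pOK) confint(fit)["p", "upper"] else NA_real_,
        kHat = if (ok && "k" %in% names(coef(fit))) coef(fit)[["k"]]
               else NA_real_,
        convHat = conv$estimate,
        convLower = conv$lower, convUpper = conv$upper)
    }
  }
  res <- do.call(rbind, rows)
  q3 <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    unname(quantile(x, c(0.25, 0.5, 0.75)))
  }
  summ <- do.call(rbind, lapply(split(res, res$region), function(s) {
    qp <- q3(s$pHat); ql <- q3(s$pLower); qu <- q3(s$pUpper)
    qc <- q3(s$convHat); qcu <- q3(s$convUpper)
    data.frame(region = s$region[1L], p = s$p[1L], k = s$k[1L], N = s$N[1L],
               n = s$n[1L], ntotal = s$ntotal[1L],
               ruleOfThree = s$ruleOfThree[1L],
               replicates = nrow(s),
               successRate = mean(s$pSuccess),
               pHatQ25 = qp[1L], pHatMed = qp[2L], pHatQ75 = qp[3L],
               pLowerMed = ql[2L], pUpperMed = qu[2L],
               convMed = qc[2L], convUpperMed = qcu[2L])
  }))
  rownames(summ) <- NULL
  structure(list(replicates = res, summary = summ,
                 seed = seed, fixK = fixK, kernel = kernel),
            class = "gridResult")
}

#' @export
print.gridResult <- function(x, ...) {
  cat(sprintf("Grid experiment: %d regions x %d replicates (%s kernel%s)\n",
              nrow(x$summary), max(x$summary$replicates), x$kernel,
              if (is.null(x$fixK)) ", all parameters unknown"
              else sprintf(", k fixed at %g", x$fixK)))
  cat(sprintf("  overall interval-estimation success for p: %.1f%%\n",
              100 * mean(x$replicates$pSuccess)))
  invisible(x)
}
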