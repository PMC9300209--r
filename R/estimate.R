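## Maximum-likelihood fitting of (p, k, deltaT, sigmaC) from bulk-sample Cq
## quartets, with Wald CIs from the observed information on the transformed
## scale (logit for p, log for the positive parameters).

.freqParNames <- c("p", "k", "deltaT", "sigmaC")

.toNatural <- function(tv, free) {
  out <- numeric(length(tv))
  names(out) <- free
  for (i in seq_along(free))
    out[i] <- if (free[i] == "p") plogis(tv[i]) else exp(tv[i])
  out
}

#' Wald confidence intervals from an observed-information matrix
#'
#' Inverts the Hessian of the negative log-likelihood at the optimum
#' (transformed scale). The standard error of parameter \eqn{j} is the square
#' root of the \eqn{j}th diagonal element of the inverse; a non-positive
#' diagonal element (or a singular matrix) marks that parameter's interval as
#' unavailable rather than raising an error, mirroring the \code{NA} returns
#' of the estimation routine.
#'
#' @param estimate numeric vector of parameter estimates on the transformed
#'   scale.
#' @param hessian square symmetric matrix of the same dimension (negative
#'   log-likelihood curvature).
#' @param level confidence level (default 0.95).
#' @return list with \code{se}, \code{lower}, \code{upper} (transformed
#'   scale; \code{NA} where unavailable), logical \code{paramSuccess} and
#'   overall \code{success}.
#' @examples
#' ciFromHessian(c(0, 1), diag(c(4, 25)))  # SEs 1/2 and 1/5
#' @export
ciFromHessian <- function(estimate, hessian, level = 0.95) {
  d <- length(estimate)
  stopifnot(is.matrix(hessian), nrow(hessian) == d, ncol(hessian) == d)
  zq <- qnorm(1 - (1 - level) / 2)
  inv <- tryCatch(solve(hessian), error = function(e) NULL)
  se <- rep(NA_real_, d)
  ok <- rep(FALSE, d)
  if (!is.null(inv)) {
    dg <- diag(inv)
    ok <- is.finite(dg) & dg > 0
    se[ok] <- sqrt(dg[ok])
  }
  list(se = se,
       lower = ifelse(ok, estimate - zq * se, NA_real_),
       upper = ifelse(ok, estimate + zq * se, NA_real_),
       paramSuccess = ok,
       success = all(ok))
}

#' Estimate a population allele frequency from bulk-sample Cq quartets
#'
#' Simultaneous maximum-likelihood estimation of the population R-allele
#' frequency \code{p}, the gamma shape \code{k} of the individual DNA yield,
#' the target content ratio \code{deltaT} and the Cq error SD \code{sigmaC}
#' from the Delta-Cq pairs of \code{N >= 2} bulk samples, with the residue
#' rate \code{z} and efficiency \code{eta} fixed from calibration. The
#' negative log-likelihood (\code{\link{totalNegLoglik}}) is minimized by a
#' Newton-type iteration (\code{\link[stats]{nlm}}) on a transformed scale
#' (logit \code{p}, log for the rest), so the back-transformed intervals
#' respect the parameter domains. Wald CIs come from the inverse Hessian at
#' the optimum; a parameter whose inverse-Hessian diagonal is not positive is
#' reported without an interval and flags the fit as unsuccessful
#' (\code{\link{fitSuccess}}).
#'
#' Starting values: \code{k} from 1 (fitting always starts at the exponential
#' yield distribution, which is the numerically stable choice), \code{p} from
#' the conventional \eqn{(1+\eta)^{-\overline{\Delta\Delta\tau}}} estimate
#' clipped to [0.001, 0.999], \code{deltaT} from 1 and \code{sigmaC} from 0.3.
#'
#' @param data a \linkS4class{BulkCqData}, or a data.frame with columns
#'   \code{dtauW}, \code{dtauD}, \code{n}.
#' @param z fixed residue rate of the off-target allele (> 0).
#' @param eta fixed per-cycle amplification efficiency (> 0).
#' @param kernel \code{"beta"} (default; single-integral marginal) or
#'   \code{"gamma"} (double-integral compatibility path).
#' @param fixK \code{NULL} to estimate the gamma shape, or a positive value to
#'   hold it fixed (e.g. \code{fixK = 1}).
#' @param start optional named list overriding the documented starting values
#'   (natural scale).
#' @param level confidence level (default 0.95).
#' @param engine \code{"quadrature"} (fast fixed-rule marginalization) or
#'   \code{"adaptive"}.
#' @param gradtol,iterlim convergence controls passed to
#'   \code{\link[stats]{nlm}}.
#' @param quadNodes Gauss-Legendre nodes per quadrature panel of the
#'   fixed-rule marginalization. The default is tuned for assay-scale Cq
#'   noise (\code{sigmaC} of roughly 0.05 cycles or more); raise it (e.g. to
#'   32) when fitting data with much smaller measurement error, whose
#'   likelihood features are narrower than the default panel resolution.
#' @return A \linkS4class{FreqFit}.
#' @examples
#' d <- simulateBulkCq(SimDesign(p = 0.25, k = 1, nPerSample = 8,
#'                               nSamples = 8), seed = 7)
#' fit <- estimateFreq(d, z = 0.0016, eta = 0.97)
#' coef(fit); confint(fit)
#' @export
estimateFreq <- function(data, z, eta, kernel = c("beta", "gamma"),
                         fixK = NULL, start = NULL, level = 0.95,
                         engine = c("quadrature", "adaptive"),
                         gradtol = 1e-6, iterlim = 200L, quadNodes = 8L) {
  kernel <- match.arg(kernel)
  engine <- match.arg(engine)
  .assertScalarPositive(z, "z")
  .assertScalarPositive(eta, "eta")
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
  nvec <- as.integer(dd$n)

  ## documented starting values
  p0 <- conventionalFreq(dd$ddtau, eta)$estimate
  s0 <- list(p = min(max(p0, 1e-3), 1 - 1e-3), k = 1, deltaT = 1, sigmaC = 0.3)
  if (!is.null(start)) s0[names(start)] <- start

  free <- .freqParNames
  fixed <- c(z = z, eta = eta)
  if (!is.null(fixK)) {
    .assertScalarPositive(fixK, "fixK")
    free <- setdiff(free, "k")
    fixed <- c(fixed, k = fixK)
  }
  tv0 <- vapply(free, function(nm)
    if (nm == "p") qlogis(s0$p) else log(s0[[nm]]), numeric(1L))

  cache <- .nodeCache()
  negll <- function(tv) {
    th <- .toNatural(tv, free)
    kk <- if (is.null(fixK)) th[["k"]] else fixK
    val <- tryCatch(
      -sum(.logLikSamples(dd$dtauW, dd$dtauD, nvec, th[["p"]], kk,
                          th[["deltaT"]], th[["sigmaC"]], z, eta,
                          kernel = kernel, engine = engine, cache = cache,
                          nGL = quadNodes)),
      error = function(e) NaN)
    if (!is.finite(val)) 1e12 else val   # keep the iteration alive
  }

  opt <- suppressWarnings(nlm(negll, tv0, hessian = TRUE, gradtol = gradtol,
                              iterlim = iterlim))
  est_t <- opt$estimate
  est <- .toNatural(est_t, free)
  ci_t <- ciFromHessian(est_t, opt$hessian, level = level)
  lower <- upper <- rep(NA_real_, length(free))
  for (i in seq_along(free)) {
    if (ci_t$paramSuccess[i]) {
      bt <- if (free[i] == "p") plogis else exp
      lower[i] <- bt(ci_t$lower[i])
      upper[i] <- bt(ci_t$upper[i])
    }
  }
  ci <- cbind(lower = lower, upper = upper)
  rownames(ci) <- free
  new("FreqFit",
      estimate = est,
      se = setNames(ci_t$se, free),
      ci = ci,
      paramSuccess = setNames(ci_t$paramSuccess, free),
      success = ci_t$success,
      loglik = -opt$minimum,
      converged = .nlmConverged(opt),
      nIter = as.integer(opt$iterations),
      level = level,
      kernel = kernel,
      fixed = fixed,
      nSamples = nrow(dd))
}
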