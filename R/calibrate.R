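## Calibration of the auxiliary assay parameters from Cq measurements on DNA
## solutions with known allele-mixing ratios, and the associated linearity /
## homoscedasticity diagnostics.

.calibParNames <- c("meanDNA", "deltaT", "deltaB", "sigmaC", "z", "eta")

#' Expected Cq for a known-ratio calibration sample
#'
#' The four conditional means of the Cq model when the total template amount
#' is \code{meanDNA} (relative to the threshold) and the R fraction is the
#' known mixing \code{ratio}: with \eqn{L = \ln(1+\eta)},
#' \deqn{\tau_{H0} = -\ln(\mathrm{meanDNA})/L,\quad
#'       \tau_{T0} = -\ln(\delta_T\,\mathrm{meanDNA})/L,}
#' \deqn{\tau_{H1} = -\ln(\delta_B\,\mathrm{meanDNA})/L,\quad
#'       \tau_{T1} = -\ln\{\delta_B \delta_T (ratio + z(1-ratio))\,
#'       \mathrm{meanDNA}\}/L.}
#'
#' @param params a \linkS4class{QpcrParams} (its \code{meanDNA} slot is the
#'   total template of the calibration solution).
#' @param ratio known mixing ratio in [0, 1] (vectorized).
#' @param gene \code{"housek"} or \code{"target"} (vectorized).
#' @param condition 0 (control / undigested) or 1 (test / digested)
#'   (vectorized).
#' @return numeric vector of expected Cq values.
#' @examples
#' p <- QpcrParams(eta = 0.9712, deltaT = 1, deltaB = 1, z = 0.001564,
#'                 meanDNA = 1.256e-6)
#' knownCqMean(p, ratio = 1, gene = "housek", condition = 0)  # approx 20.02
#' @export
knownCqMean <- function(params, ratio, gene, condition) {
  stopifnot(is(params, "QpcrParams"))
  nn <- max(length(ratio), length(gene), length(condition))
  ratio <- rep_len(as.numeric(ratio), nn)
  gene <- rep_len(as.character(gene), nn)
  condition <- rep_len(as.integer(condition), nn)
  if (any(!is.finite(ratio)) || any(ratio < 0 | ratio > 1))
    stop("'ratio' must lie in [0, 1]", call. = FALSE)
  if (!all(gene %in% c("housek", "target")))
    stop("'gene' must be 'housek' or 'target'", call. = FALSE)
  if (!all(condition %in% c(0L, 1L)))
    stop("'condition' must be 0 or 1", call. = FALSE)
  L <- log(1 + params@eta)
  lm0 <- log(params@meanDNA) - log(params@xTheta)
  lq <- lm0 +
    ifelse(gene == "target", log(params@deltaT), 0) +
    ifelse(condition == 1L, log(params@deltaB), 0) +
    ifelse(gene == "target" & condition == 1L,
           log(ratio + params@z * (1 - ratio)), 0)
  -lq / L
}

.calibStart <- function(d) {
  L0 <- log(2)
  mcell <- function(g, cc, r = NULL) {
    sel <- d$gene == g & d$condition == cc
    if (!is.null(r)) sel <- sel & d$ratio %in% r
    if (!any(sel)) NA_real_ else mean(d$cq[sel])
  }
  h0 <- mcell("housek", 0L); t0 <- mcell("target", 0L)
  h1 <- mcell("housek", 1L); t1r0 <- mcell("target", 1L, r = 0)
  meanDNA0 <- if (is.finite(h0)) exp(-L0 * h0) else
    if (is.finite(h1)) exp(-L0 * h1) else 1e-6
  deltaT0 <- if (is.finite(t0) && is.finite(h0)) exp(-L0 * (t0 - h0)) else 1
  deltaB0 <- if (is.finite(h1) && is.finite(h0)) exp(-L0 * (h1 - h0)) else 0.5
  z0 <- if (is.finite(t1r0) && is.finite(h1))
    max(1e-6, exp(-L0 * (t1r0 - h1)) / deltaT0) else 1e-3
  list(meanDNA = max(meanDNA0, 1e-300), deltaT = deltaT0, deltaB = deltaB0,
       sigmaC = 0.3, z = min(z0, 0.5), eta = 1)
}

#' Calibrate auxiliary assay parameters from known-ratio Cq data
#'
#' Joint maximum-likelihood estimation of the six auxiliary parameters
#' (\code{meanDNA}, \code{deltaT}, \code{deltaB}, \code{sigmaC}, \code{z},
#' \code{eta}) from Cq measurements on DNA solutions with known allele-mixing
#' ratios. Each observed Cq is modelled as
#' \eqn{N(\mathrm{knownCqMean}(\cdot), \sigma_c^2)}; \code{sigmaC} is a free
#' likelihood parameter, not a plug-in residual SD, so it carries a CI like
#' the others. All six parameters are fitted on the log scale and the Wald
#' intervals are therefore multiplicatively symmetric around the estimates.
#'
#' With \code{paired = TRUE} a complete Cq quartet is required for every
#' (ratio, replicate); \code{paired = FALSE} (default) accepts whatever cells
#' exist -- e.g. designs measuring the undigested condition only at ratio 1.
#' The likelihood is the same product of independent normals either way.
#'
#' @param data a \linkS4class{KnownRatioData} (or a data.frame with its
#'   columns).
#' @param paired require complete quartets (see Details).
#' @param start optional named list of natural-scale starting values
#'   overriding the data-driven defaults.
#' @param level confidence level.
#' @param gradtol,steptol,iterlim convergence controls, mapped to the
#'   \code{ftol}, \code{ptol} and \code{maxiter} of the Levenberg-Marquardt
#'   iteration (\code{\link[minpack.lm]{nls.lm}}).
#' @return A \linkS4class{CalibFit}.
#' @examples
#' p <- QpcrParams(eta = 0.9712, deltaT = 1.17, deltaB = 0.2361,
#'                 z = 0.001564, sigmaC = 0.2376, meanDNA = 1.256e-6)
#' d <- simulateKnownRatio(p, ratio = c(0, 0.01, 0.1, 0.5, 1),
#'                         replicates = 4, seed = 1)
#' calibrateKnown(d)
#' @export
calibrateKnown <- function(data, paired = FALSE, start = NULL, level = 0.95,
                           gradtol = 1e-8, steptol = 1e-10, iterlim = 500L) {
  if (!is(data, "KnownRatioData"))
    data <- do.call(KnownRatioData, as.list(as.data.frame(data)[
      c("ratio", "gene", "condition", "replicate", "cq")]))
  d <- as.data.frame(data)
  if (paired) {
    counts <- table(paste(d$ratio, d$replicate))
    cells <- tapply(paste(d$gene, d$condition), paste(d$ratio, d$replicate),
                    function(x) length(unique(x)))
    if (any(cells < 4L))
      stop("paired = TRUE requires a complete Cq quartet for every ",
           "(ratio, replicate); incomplete: ",
           paste(names(cells)[cells < 4L], collapse = ", "),
           ". Use paired = FALSE for incomplete designs.", call. = FALSE)
  }
  ## identifiability pre-checks, naming the offending parameter
  if (!any(d$condition == 1L & d$gene == "target" & d$ratio < 1))
    stop("parameter 'z' is not identifiable: no digested/test target ",
         "observations with ratio < 1", call. = FALSE)
  if (!any(d$condition == 0L))
    stop("parameters 'meanDNA' and 'deltaB' are not separable: no ",
         "control/undigested observations", call. = FALSE)
  if (!any(d$condition == 1L))
    stop("parameter 'deltaB' is not identifiable: no digested/test ",
         "observations", call. = FALSE)
  if (!any(d$gene == "housek"))
    stop("parameter 'deltaT' is not identifiable: no housekeeping-gene ",
         "observations", call. = FALSE)
  if (length(unique(d$ratio)) < 2L)
    stop("at least two distinct mixing ratios are required", call. = FALSE)

  s0 <- .calibStart(d)
  if (!is.null(start)) s0[names(start)] <- start
  struct <- setdiff(.calibParNames, "sigmaC")
  tv0 <- log(unlist(s0[struct]))

  tgt <- d$gene == "target"
  dig <- d$condition == 1L
  nObs <- nrow(d)
  predCq <- function(th) {
    L <- log(1 + th[["eta"]])
    lq <- log(th[["meanDNA"]]) + tgt * log(th[["deltaT"]]) +
      dig * log(th[["deltaB"]]) +
      ifelse(tgt & dig, log(d$ratio + th[["z"]] * (1 - d$ratio)), 0)
    -lq / L
  }
  ## sigmaC has a closed-form conditional MLE (the RMS residual), so it is
  ## profiled out and only the 5 structural parameters are searched. Over
  ## those, maximizing the likelihood is exactly a nonlinear least-squares
  ## problem, solved by Levenberg-Marquardt -- which stays accurate along
  ## softly identified directions and in the zero-residual limit, where a
  ## generic Newton iteration on the joint likelihood stalls.
  residFun <- function(tv) {
    th <- exp(tv)
    if (any(!is.finite(th))) return(rep(1e6, nObs))
    names(th) <- struct
    r <- d$cq - predCq(th)
    if (any(!is.finite(r))) rep(1e6, nObs) else r
  }
  negllFull <- function(tv) {
    th <- exp(tv)
    if (any(!is.finite(th))) return(1e12)
    names(th) <- .calibParNames
    val <- -sum(dnorm(d$cq, predCq(th), th[["sigmaC"]], log = TRUE))
    if (!is.finite(val)) 1e12 else val
  }
  opt <- minpack.lm::nls.lm(par = tv0, fn = residFun,
                            control = minpack.lm::nls.lm.control(
                              ftol = gradtol, ptol = steptol,
                              maxiter = min(iterlim, 1024L)))
  tvHat <- unname(coef(opt))
  thHat <- setNames(exp(tvHat), struct)
  sigmaHat <- sqrt(mean((d$cq - predCq(thHat))^2))
  tvFull <- c(tvHat[1:3], log(sigmaHat), tvHat[4:5])
  est <- setNames(exp(tvFull), .calibParNames)
  hess <- tryCatch(stats::optimHess(tvFull, negllFull),
                   error = function(e) matrix(NA_real_, 6L, 6L))
  ci_t <- ciFromHessian(tvFull, hess, level = level)
  ci <- cbind(lower = ifelse(ci_t$paramSuccess, exp(ci_t$lower), NA_real_),
              upper = ifelse(ci_t$paramSuccess, exp(ci_t$upper), NA_real_))
  rownames(ci) <- .calibParNames
  new("CalibFit",
      estimate = est,
      se = setNames(ci_t$se, .calibParNames),
      ci = ci,
      paramSuccess = setNames(ci_t$paramSuccess, .calibParNames),
      success = ci_t$success,
      loglik = -negllFull(tvFull),
      converged = opt$info %in% 1:4,
      nIter = as.integer(opt$niter),
      level = level,
      nObs = nrow(d),
      paired = paired)
}

#' Linearity and homoscedasticity diagnostics for known-ratio data
#'
#' Reproduces the classical verification of a (RED-)\eqn{\Delta\Delta}Cq
#' assay: per replicate, the \eqn{\Delta\Delta\tau} of each mixing ratio is
#' formed against that replicate's control \eqn{\Delta\tau_W} measured at
#' ratio 1 (designs often measure the undigested condition only there; reusing
#' it leaves the point estimates unaffected). The observed values are then
#' regressed on their theoretical counterparts:
#' \itemize{
#'   \item \code{scale = "ddcq"}: response \eqn{\Delta\Delta\tau}, predictor
#'     \eqn{-\ln\{z(1-Y_R) + Y_R\}/\ln(1+\eta)};
#'   \item \code{scale = "linear"}: response \eqn{(1+\eta)^{-\Delta\Delta\tau}},
#'     predictor \eqn{z(1-Y_R) + Y_R}.
#' }
#' Reported are the OLS intercept and slope, the adjusted \eqn{R^2}, and the
#' Breusch-Pagan statistic in its LM form \eqn{N R^2_{aux}} from regressing
#' the squared residuals on the predictor (df = 1), with its chi-square
#' p-value. A homoscedastic assay should pass on the Cq (log) scale and
#' typically fails on the linear scale.
#'
#' @param data a \linkS4class{KnownRatioData}.
#' @param z,eta fitted auxiliary parameters used to form the theoretical
#'   predictor.
#' @param scale \code{"ddcq"} or \code{"linear"}.
#' @return list of class \code{"cqDiagnostics"}: \code{intercept},
#'   \code{slope}, \code{adjR2}, \code{bp}, \code{bpDf}, \code{bpP},
#'   \code{scale}, \code{n}, and the underlying \code{model} (an \code{lm}).
#' @export
linearityDiagnostics <- function(data, z, eta, scale = c("ddcq", "linear")) {
  scale <- match.arg(scale)
  .assertScalarPositive(z, "z")
  .assertScalarPositive(eta, "eta")
  d <- as.data.frame(data)
  ## per-replicate control Delta-Cq at ratio 1
  reps <- unique(d$replicate)
  dtw <- vapply(reps, function(r) {
    t0 <- d$cq[d$replicate == r & d$ratio == 1 & d$gene == "target" &
                 d$condition == 0L]
    h0 <- d$cq[d$replicate == r & d$ratio == 1 & d$gene == "housek" &
                 d$condition == 0L]
    if (!length(t0) || !length(h0)) NA_real_ else mean(t0) - mean(h0)
  }, numeric(1L))
  names(dtw) <- reps
  ## per (ratio, replicate) test Delta-Cq
  dd <- expand.grid(ratio = sort(unique(d$ratio)), replicate = reps,
                    stringsAsFactors = FALSE)
  dd$ddtau <- mapply(function(rt, rp) {
    t1 <- d$cq[d$replicate == rp & d$ratio == rt & d$gene == "target" &
                 d$condition == 1L]
    h1 <- d$cq[d$replicate == rp & d$ratio == rt & d$gene == "housek" &
                 d$condition == 1L]
    if (!length(t1) || !length(h1)) return(NA_real_)
    (mean(t1) - mean(h1)) - dtw[[rp]]
  }, dd$ratio, dd$replicate)
  dd <- dd[is.finite(dd$ddtau), ]
  if (nrow(dd) < 3L)
    stop("need at least 3 (ratio, replicate) points with computable ",
         "Delta-Delta-Cq", call. = FALSE)
  L <- log(1 + eta)
  if (scale == "ddcq") {
    x <- -log(z * (1 - dd$ratio) + dd$ratio) / L
    y <- dd$ddtau
  } else {
    x <- z * (1 - dd$ratio) + dd$ratio
    y <- (1 + eta)^(-dd$ddtau)
  }
  fit <- lm(y ~ x)
  r2adj <- summary(fit)$adj.r.squared
  r2 <- residuals(fit)^2
  bp <- if (var(r2) < .Machine$double.eps^2) 0 else   # exact fit: no signal
    length(x) * summary(lm(r2 ~ x))$r.squared
  structure(list(intercept = unname(coef(fit)[1L]),
                 slope = unname(coef(fit)[2L]),
                 adjR2 = r2adj,
                 bp = bp, bpDf = 1L,
                 bpP = pchisq(bp, 1L, lower.tail = FALSE),
                 scale = scale, n = length(x), model = fit),
            class = "cqDiagnostics")
}

#' @export
print.cqDiagnostics <- function(x, ...) {
  cat(sprintf("Known-ratio linearity diagnostics (%s scale, %d points)\n",
              x$scale, x$n))
  cat(sprintf("  intercept = %.5g, slope = %.5g, adjusted R^2 = %.5g\n",
              x$intercept, x$slope, x$adjR2))
  cat(sprintf("  Breusch-Pagan: BP = %.5g, df = %d, p = %.4g\n",
              x$bp, x$bpDf, x$bpP))
  invisible(x)
}
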