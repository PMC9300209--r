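## Deterministic forward model: pool composition -> DNA quantities -> Cq.

#' Delta-Cq pairs from Cq quartets
#'
#' For each bulk sample computes the two relative-quantification observables
#' \deqn{\Delta\tau_W = \tau_{TW} - \tau_{HW}, \quad
#'       \Delta\tau_D = \tau_{TD} - \tau_{HD}, \quad
#'       \Delta\Delta\tau = \Delta\tau_D - \Delta\tau_W.}
#' The subtraction cancels the total-template and digestion effects
#' (\eqn{X_\Theta}, \eqn{\delta_B}), so only the allele ratio and
#' \eqn{\delta_T} remain in the expectation.
#'
#' @param object a \linkS4class{BulkCqData}, or a matrix / data.frame with
#'   columns \code{housek0}, \code{target0}, \code{housek1}, \code{target1}.
#' @return data.frame with columns \code{dtauW}, \code{dtauD}, \code{ddtau}.
#' @examples
#' deltaCq(data.frame(housek0 = 20, target0 = 19.8,
#'                    housek1 = 22.1, target1 = 24))
#' @export
setGeneric("deltaCq", function(object) standardGeneric("deltaCq"))

.deltaCqFromMatrix <- function(cq) {
  if (!all(.cqCols %in% colnames(cq)))
    stop("need columns ", paste(.cqCols, collapse = ", "), call. = FALSE)
  cq <- as.matrix(cq[, .cqCols, drop = FALSE])
  .assertFinite(cq, "Cq quartet")
  dtauW <- cq[, "target0"] - cq[, "housek0"]
  dtauD <- cq[, "target1"] - cq[, "housek1"]
  data.frame(dtauW = unname(dtauW), dtauD = unname(dtauD),
             ddtau = unname(dtauD - dtauW))
}

#' @rdname deltaCq
#' @export
setMethod("deltaCq", "BulkCqData", function(object)
  .deltaCqFromMatrix(object@cq))

#' @rdname deltaCq
#' @export
setMethod("deltaCq", "data.frame", function(object)
  .deltaCqFromMatrix(as.matrix(object)))

#' @rdname deltaCq
#' @export
setMethod("deltaCq", "matrix", function(object) .deltaCqFromMatrix(object))

#' Noise-free expected Cq quartet for given allelic template amounts
#'
#' Evaluates the deterministic part of the Cq model at measurement error
#' \eqn{\varepsilon_c = 0}:
#' \deqn{\tau_{HW} = \frac{\ln X_\Theta - \ln(X_R + X_S)}{\ln(1+\eta)}}
#' and analogously for the other three channels, where the target gene scales
#' by \eqn{\delta_T}, the digested condition by \eqn{\delta_B}, and digestion
#' replaces \eqn{X_R + X_S} by \eqn{X_R + z X_S} on the target locus.
#'
#' @param params a \linkS4class{QpcrParams}.
#' @param xR,xS non-negative allelic template amounts (vectors, recycled);
#'   \code{xR + xS} must be positive.
#' @return data.frame with columns \code{housek0}, \code{target0},
#'   \code{housek1}, \code{target1}.
#' @examples
#' p <- QpcrParams(eta = 1, deltaT = 1, deltaB = 1)
#' expectedCq(p, xR = 1e-6, xS = 0)  # all four approximately 19.93
#' @export
expectedCq <- function(params, xR, xS) {
  stopifnot(is(params, "QpcrParams"))
  nn <- max(length(xR), length(xS))
  xR <- rep_len(as.numeric(xR), nn)
  xS <- rep_len(as.numeric(xS), nn)
  if (any(!is.finite(xR)) || any(!is.finite(xS)) || any(xR < 0) || any(xS < 0))
    stop("'xR' and 'xS' must be finite and non-negative", call. = FALSE)
  tot <- xR + xS
  totD <- xR + params@z * xS
  if (any(tot == 0)) stop("xR + xS must be positive", call. = FALSE)
  if (any(totD == 0)) stop("xR + z*xS must be positive", call. = FALSE)
  L <- log(1 + params@eta)
  lx <- log(params@xTheta)
  data.frame(
    housek0 = (lx - log(tot)) / L,
    target0 = (lx - log(params@deltaT) - log(tot)) / L,
    housek1 = (lx - log(params@deltaB) - log(tot)) / L,
    target1 = (lx - log(params@deltaB) - log(params@deltaT) - log(totD)) / L)
}

#' Theoretical Delta-Delta-Cq for a given sample allele frequency
#'
#' The noise-free expectation
#' \eqn{-\ln\{z + Y_R (1-z)\} / \ln(1+\eta)}: the curve relating the true R
#' frequency in a sample to its \eqn{\Delta\Delta}Cq measure. It is 0 at
#' \eqn{Y_R = 1} and reaches \eqn{-\ln z/\ln(1+\eta)} at \eqn{Y_R = 0}
#' (finite because \eqn{z > 0}).
#'
#' @param yR sample R-allele frequency in [0, 1] (vectorized).
#' @param z residue rate (> 0).
#' @param eta amplification efficiency (> 0).
#' @return numeric vector of expected \eqn{\Delta\Delta\tau} (cycles).
#' @examples
#' theoreticalDdcq(0, z = 0.001564, eta = 0.9712)  # approx. 9.52 cycles
#' @export
theoreticalDdcq <- function(yR, z, eta) {
  .assertScalarPositive(z, "z")
  .assertScalarPositive(eta, "eta")
  if (any(!is.finite(yR)) || any(yR < 0 | yR > 1))
    stop("'yR' must lie in [0, 1]", call. = FALSE)
  -log(z + yR * (1 - z)) / log(1 + eta)
}

#' Conventional Delta-Delta-Cq frequency estimate
#'
#' The simple-averaging point estimator
#' \eqn{\hat p = (1+\eta)^{-\overline{\Delta\Delta\tau}}} together with the
#' naive interval obtained by transforming
#' \eqn{\overline{\Delta\Delta\tau} \pm z_{\alpha/2}\,\mathrm{SE}}. The
#' estimate is a frequency-scale quantity but is not constrained to [0, 1];
#' the upper interval endpoint in particular can exceed 1. The naive interval
#' exists only for comparison with the model-based estimator.
#'
#' @param ddtau numeric vector of observed \eqn{\Delta\Delta\tau} values
#'   (one per bulk sample); at least one value.
#' @param eta amplification efficiency (> 0).
#' @param level confidence level of the naive interval.
#' @return list with \code{estimate}, \code{lower}, \code{upper}, \code{mean}
#'   (mean \eqn{\Delta\Delta\tau}) and \code{se} (its standard error;
#'   \code{NA} for a single sample, in which case the interval is \code{NA}).
#' @examples
#' conventionalFreq(c(2.0, 2.2), eta = 0.971)
#' @export
conventionalFreq <- function(ddtau, eta, level = 0.95) {
  .assertScalarPositive(eta, "eta")
  if (length(ddtau) < 1L) stop("need at least one ddtau value", call. = FALSE)
  .assertFinite(ddtau, "ddtau")
  m <- mean(ddtau)
  se <- if (length(ddtau) > 1L) sd(ddtau) / sqrt(length(ddtau)) else NA_real_
  zq <- qnorm(1 - (1 - level) / 2)
  est <- (1 + eta)^(-m)
  list(estimate = est,
       lower = (1 + eta)^(-(m + zq * se)),
       upper = (1 + eta)^(-(m - zq * se)),
       mean = m, se = se)
}
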