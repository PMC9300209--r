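#' @import methods
#' @importFrom stats dnorm dbeta dbinom dgamma qbeta pbeta pgamma qgamma
#'   rnorm rbinom rgamma integrate nlm qnorm plogis qlogis sd var quantile
#'   lm residuals fitted coef pchisq median setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion
NULL

## ---------------------------------------------------------------------------
## QpcrParams: the auxiliary parameter set of the Delta-Delta-Cq assay
## ---------------------------------------------------------------------------

#' Auxiliary qPCR assay parameters
#'
#' Container for the experimental parameters of a (RED-)\eqn{\Delta\Delta}Cq
#' assay: per-cycle amplification efficiency \eqn{\eta} (amplification factor
#' \eqn{1+\eta}), the termination threshold \eqn{X_\Theta} (fixed at 1; all DNA
#' quantities are expressed relative to it), the target-to-housekeeping content
#' ratio \eqn{\delta_T}, the locus-independent template change rate of the
#' digestion step \eqn{\delta_B}, the residue rate of the susceptible allele
#' after digestion (or the off-target amplification fraction) \eqn{z}, the Cq
#' measurement error SD \eqn{\sigma_c}, and the mean per-individual template
#' amount relative to the threshold (\code{meanDNA}).
#'
#' @slot eta numeric(1), per-cycle efficiency; amplification factor is
#'   \code{1 + eta}.
#' @slot xTheta numeric(1), amplification termination threshold (fixed 1).
#' @slot deltaT numeric(1), relative content of the target gene to the
#'   housekeeping gene.
#' @slot deltaB numeric(1), locus-independent template change rate accompanying
#'   digestion.
#' @slot z numeric(1), residue rate of the off-target allele (> 0).
#' @slot sigmaC numeric(1), SD of the Cq measurement error.
#' @slot meanDNA numeric(1), mean per-individual template relative to
#'   \code{xTheta}.
#' @export
setClass("QpcrParams",
  representation(eta = "numeric", xTheta = "numeric", deltaT = "numeric",
                 deltaB = "numeric", z = "numeric", sigmaC = "numeric",
                 meanDNA = "numeric"))

setValidity("QpcrParams", function(object) {
  msg <- character()
  for (s in c("eta", "xTheta", "deltaT", "deltaB", "z", "sigmaC", "meanDNA")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("slot '%s' must be a single positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QpcrParams object
#'
#' Defaults are the parameter values presupposed in the package's numerical
#' experiments (estimated from a spider-mite RED-\eqn{\Delta\Delta}Cq
#' calibration): \eqn{\delta_T = 1.2}, \eqn{\delta_B = 0.24},
#' \eqn{z = 0.0016}, \eqn{\eta = 0.97}, \eqn{\sigma_c = 0.2}.
#'
#' @param eta per-cycle amplification efficiency (> 0).
#' @param deltaT relative target-gene content (> 0).
#' @param deltaB digestion template change rate (> 0).
#' @param z residue rate of the off-target allele (> 0). A value \eqn{\ge 1}
#'   triggers a warning (the assay is not discriminating) but is not an error.
#' @param sigmaC Cq measurement error SD (> 0).
#' @param meanDNA mean per-individual template relative to the threshold (> 0).
#' @param xTheta termination threshold; kept at 1 (quantities are relative).
#' @return A \linkS4class{QpcrParams} object.
#' @examples
#' QpcrParams()
#' QpcrParams(eta = 0.9712, z = 0.001564)
#' @export
QpcrParams <- function(eta = 0.97, deltaT = 1.2, deltaB = 0.24, z = 0.0016,
                       sigmaC = 0.2, meanDNA = 1e-6, xTheta = 1) {
  if (is.finite(z) && z >= 1)
    warning("'z' >= 1: the assay does not discriminate alleles", call. = FALSE)
  new("QpcrParams", eta = eta, xTheta = xTheta, deltaT = deltaT,
      deltaB = deltaB, z = z, sigmaC = sigmaC, meanDNA = meanDNA)
}

#' @describeIn QpcrParams-class accessor for \code{eta}.
#' @param object,x a \code{QpcrParams} object.
#' @export
setGeneric("EPCR", function(object) standardGeneric("EPCR"))
#' @rdname QpcrParams-class
#' @export
setMethod("EPCR", "QpcrParams", function(object) object@eta)

#' @rdname QpcrParams-class
#' @export
setGeneric("targetScale", function(object) standardGeneric("targetScale"))
#' @rdname QpcrParams-class
#' @export
setMethod("targetScale", "QpcrParams", function(object) object@deltaT)

#' @rdname QpcrParams-class
#' @export
setGeneric("baseChange", function(object) standardGeneric("baseChange"))
#' @rdname QpcrParams-class
#' @export
setMethod("baseChange", "QpcrParams", function(object) object@deltaB)

#' @rdname QpcrParams-class
#' @export
setGeneric("zeroAmount", function(object) standardGeneric("zeroAmount"))
#' @rdname QpcrParams-class
#' @export
setMethod("zeroAmount", "QpcrParams", function(object) object@z)

#' @rdname QpcrParams-class
#' @export
setGeneric("sdMeasure", function(object) standardGeneric("sdMeasure"))
#' @rdname QpcrParams-class
#' @export
setMethod("sdMeasure", "QpcrParams", function(object) object@sigmaC)

#' @rdname QpcrParams-class
#' @export
setGeneric("meanDNA", function(object) standardGeneric("meanDNA"))
#' @rdname QpcrParams-class
#' @export
setMethod("meanDNA", "QpcrParams", function(object) object@meanDNA)

setMethod("show", "QpcrParams", function(object) {
  cat("QpcrParams (Delta-Delta-Cq assay parameters)\n")
  cat(sprintf("  amplification: 1 + eta = %.4g\n", 1 + object@eta))
  cat(sprintf("  targetScale (deltaT) = %.4g, baseChange (deltaB) = %.4g\n",
              object@deltaT, object@deltaB))
  cat(sprintf("  zeroAmount (z) = %.4g, sdMeasure (sigma_c) = %.4g\n",
              object@z, object@sigmaC))
  cat(sprintf("  meanDNA = %.4g (relative to threshold X_Theta = %.4g)\n",
              object@meanDNA, object@xTheta))
})

## ---------------------------------------------------------------------------
## BulkCqData: Cq quartets over N bulk samples
## ---------------------------------------------------------------------------

#' Cq quartets measured on bulk samples
#'
#' One row per bulk (pooled) DNA sample: the pool size \code{n} and the four
#' quantification-cycle values \code{housek0}, \code{target0} (control /
#' undigested condition) and \code{housek1}, \code{target1} (test / digested
#' condition). For the allele-specific-primer protocol the condition-0 columns
#' hold the pure-R control and condition-1 the test sample; downstream code is
#' identical and \code{protocol} records which labels apply.
#'
#' @slot sampleId character, sample identifiers.
#' @slot n integer, pool sizes (haploid individuals per bulk sample).
#' @slot cq numeric matrix with columns \code{housek0}, \code{target0},
#'   \code{housek1}, \code{target1}.
#' @slot protocol character(1), \code{"RED"} or \code{"specific-primer"}.
#' @slot metadata list, free-form (the simulator stores the latent pool state
#'   here).
#' @export
setClass("BulkCqData",
  representation(sampleId = "character", n = "integer", cq = "matrix",
                 protocol = "character", metadata = "list"))

.cqCols <- c("housek0", "target0", "housek1", "target1")

setValidity("BulkCqData", function(object) {
  msg <- character()
  N <- nrow(object@cq)
  if (!identical(colnames(object@cq), .cqCols))
    msg <- c(msg, "cq matrix must have columns housek0, target0, housek1, target1")
  if (length(object@sampleId) != N || length(object@n) != N)
    msg <- c(msg, "sampleId, n and cq rows must have equal length")
  if (any(!is.finite(object@cq)))
    msg <- c(msg, "all Cq values must be finite")
  if (any(object@n < 1L))
    msg <- c(msg, "all pool sizes n must be >= 1")
  if (!object@protocol %in% c("RED", "specific-primer"))
    msg <- c(msg, "protocol must be 'RED' or 'specific-primer'")
  if (length(msg)) msg else TRUE
})

#' Construct a BulkCqData object
#'
#' @param housek0,target0,housek1,target1 numeric vectors of Cq values
#'   (housekeeping/target gene under the control=0 and test=1 conditions).
#' @param n integer vector (or scalar, recycled) of pool sizes.
#' @param sampleId optional character vector of sample names.
#' @param protocol \code{"RED"} (restriction-enzyme digestion) or
#'   \code{"specific-primer"}; bookkeeping only.
#' @param metadata optional list.
#' @return A \linkS4class{BulkCqData} object.
#' @examples
#' BulkCqData(housek0 = c(20, 21), target0 = c(20.5, 21.4),
#'            housek1 = c(22, 23), target1 = c(24, 30), n = 8)
#' @export
BulkCqData <- function(housek0, target0, housek1, target1, n,
                       sampleId = NULL, protocol = c("RED", "specific-primer"),
                       metadata = list()) {
  protocol <- match.arg(protocol)
  cq <- cbind(housek0 = as.numeric(housek0), target0 = as.numeric(target0),
              housek1 = as.numeric(housek1), target1 = as.numeric(target1))
  N <- nrow(cq)
  n <- as.integer(rep_len(n, N))
  if (is.null(sampleId)) sampleId <- sprintf("bulk%02d", seq_len(N))
  new("BulkCqData", sampleId = as.character(sampleId), n = n, cq = cq,
      protocol = protocol, metadata = metadata)
}

#' @rdname BulkCqData-class
#' @param object,x a \code{BulkCqData} object.
#' @export
setGeneric("poolSize", function(object) standardGeneric("poolSize"))
#' @rdname BulkCqData-class
#' @export
setMethod("poolSize", "BulkCqData", function(object) object@n)

#' @rdname BulkCqData-class
#' @export
setGeneric("cqValues", function(object) standardGeneric("cqValues"))
#' @rdname BulkCqData-class
#' @export
setMethod("cqValues", "BulkCqData", function(object) object@cq)

#' @rdname BulkCqData-class
#' @export
setGeneric("latentState", function(object) standardGeneric("latentState"))
#' @rdname BulkCqData-class
#' @export
setMethod("latentState", "BulkCqData", function(object)
  object@metadata$latent)

setMethod("show", "BulkCqData", function(object) {
  cat(sprintf("BulkCqData: %d bulk samples (%s protocol), %d individuals in total\n",
              length(object@n), object@protocol, sum(object@n)))
  df <- as.data.frame(object)
  print(utils::head(df, 6L))
  if (nrow(df) > 6L) cat(sprintf("  ... and %d more samples\n", nrow(df) - 6L))
})

#' @rdname BulkCqData-class
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
setMethod("as.data.frame", "BulkCqData",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(sampleId = x@sampleId, n = x@n, as.data.frame(x@cq),
               row.names = row.names)
  })

#' @rdname BulkCqData-class
#' @param i row (sample) index.
#' @export
setMethod("[", "BulkCqData", function(x, i) {
  lat <- x@metadata$latent
  md <- x@metadata
  if (!is.null(lat)) md$latent <- lat[i, , drop = FALSE]
  new("BulkCqData", sampleId = x@sampleId[i], n = x@n[i],
      cq = x@cq[i, , drop = FALSE], protocol = x@protocol, metadata = md)
})

#' @rdname BulkCqData-class
#' @export
setMethod("length", "BulkCqData", function(x) length(x@n))

## ---------------------------------------------------------------------------
## KnownRatioData: calibration observations at known allele-mixing ratios
## ---------------------------------------------------------------------------

#' Cq observations on samples with known allele-mixing ratios
#'
#' Long-format calibration data: each row is one Cq measurement on a DNA
#' solution mixed from pure lines at a known R-allele ratio, for one gene
#' (\code{"housek"} or \code{"target"}) under one condition (0 = control /
#' undigested, 1 = test / digested). Cells may be missing for any
#' (ratio, gene, condition) combination -- the unpaired design.
#'
#' @slot data data.frame with columns \code{ratio}, \code{gene},
#'   \code{condition}, \code{replicate}, \code{cq}.
#' @export
setClass("KnownRatioData", representation(data = "data.frame"))

setValidity("KnownRatioData", function(object) {
  d <- object@data
  msg <- character()
  need <- c("ratio", "gene", "condition", "replicate", "cq")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (any(!is.finite(d$ratio)) || any(d$ratio < 0 | d$ratio > 1))
    msg <- c(msg, "ratio must lie in [0, 1]")
  if (!all(d$gene %in% c("housek", "target")))
    msg <- c(msg, "gene must be 'housek' or 'target'")
  if (!all(d$condition %in% c(0L, 1L)))
    msg <- c(msg, "condition must be 0 (control) or 1 (test)")
  if (any(!is.finite(d$cq)))
    msg <- c(msg, "all Cq values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a KnownRatioData object
#'
#' @param ratio numeric in [0, 1], the known mixing ratio
#'   \eqn{Y_R = X_R / (X_R + X_S)}.
#' @param gene \code{"housek"} or \code{"target"}.
#' @param condition 0 (control / undigested) or 1 (test / digested).
#' @param replicate replicate identifier.
#' @param cq measured Cq value.
#' @return A \linkS4class{KnownRatioData} object.
#' @export
KnownRatioData <- function(ratio, gene, condition, replicate, cq) {
  new("KnownRatioData",
      data = data.frame(ratio = as.numeric(ratio), gene = as.character(gene),
                        condition = as.integer(condition),
                        replicate = as.character(replicate),
                        cq = as.numeric(cq)))
}

#' @rdname KnownRatioData-class
#' @param x a \code{KnownRatioData} object.
#' @param row.names,optional,... conventional; unused.
#' @export
setMethod("as.data.frame", "KnownRatioData",
  function(x, row.names = NULL, optional = FALSE, ...) x@data)

setMethod("show", "KnownRatioData", function(object) {
  d <- object@data
  cat(sprintf("KnownRatioData: %d Cq observations, %d mixing ratios, %d replicates\n",
              nrow(d), length(unique(d$ratio)), length(unique(d$replicate))))
  tab <- table(gene = d$gene, condition = d$condition)
  print(tab)
})

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' Virtual parent of maximum-likelihood fit results
#'
#' @slot estimate named numeric, point estimates on the natural scale.
#' @slot se named numeric, standard errors on the transformed (optimization)
#'   scale.
#' @slot ci numeric matrix (parameters x \code{c("lower","upper")}), natural
#'   scale; \code{NA} where interval estimation failed.
#' @slot paramSuccess named logical, whether the inverse observed information
#'   gave a positive variance for each free parameter.
#' @slot success logical(1), \code{TRUE} iff CIs were obtained for every free
#'   parameter.
#' @slot loglik numeric(1), maximized log-likelihood.
#' @slot converged logical(1), optimizer termination status.
#' @slot nIter integer(1), iteration count.
#' @slot level numeric(1), confidence level.
#' @export
setClass("CqFit",
  representation("VIRTUAL",
                 estimate = "numeric", se = "numeric", ci = "matrix",
                 paramSuccess = "logical", success = "logical",
                 loglik = "numeric", converged = "logical",
                 nIter = "integer", level = "numeric"))

#' Population allele-frequency fit
#'
#' Result of \code{\link{estimateFreq}}: simultaneous MLE of the population R
#' frequency \code{p}, the gamma shape \code{k}, the target content ratio
#' \code{deltaT} and the Cq error SD \code{sigmaC}, with Wald CIs from the
#' observed information on the transformed scale (logit for \code{p}, log for
#' the rest).
#'
#' @slot kernel \code{"beta"} or \code{"gamma"} marginalization kernel.
#' @slot fixed named numeric of parameters held fixed (always \code{z} and
#'   \code{eta}; optionally \code{k}).
#' @slot nSamples integer(1), number of bulk samples fitted.
#' @export
setClass("FreqFit", contains = "CqFit",
  representation(kernel = "character", fixed = "numeric",
                 nSamples = "integer"))

#' Known-ratio calibration fit
#'
#' Result of \code{\link{calibrateKnown}}: joint MLE of the auxiliary assay
#' parameters (\code{meanDNA}, \code{deltaT}, \code{deltaB}, \code{sigmaC},
#' \code{z}, \code{eta}) from Cq data at known mixing ratios. All parameters
#' are fitted on the log scale, so CIs are multiplicatively symmetric.
#'
#' @slot nObs integer(1), number of Cq observations.
#' @slot paired logical(1), whether complete quartets were required.
#' @export
setClass("CalibFit", contains = "CqFit",
  representation(nObs = "integer", paired = "logical"))

.showFit <- function(object, head) {
  cat(head, "\n")
  ci <- object@ci
  df <- data.frame(estimate = signif(object@estimate, 4),
                   lower = signif(ci[, "lower"], 4),
                   upper = signif(ci[, "upper"], 4),
                   row.names = names(object@estimate))
  print(df)
  cat(sprintf("log-likelihood: %.4f; converged: %s; interval estimation %s\n",
              object@loglik, object@converged,
              if (isTRUE(object@success)) "succeeded" else
                "FAILED (CI unavailable for some parameter)"))
}

setMethod("show", "FreqFit", function(object) {
  .showFit(object, sprintf(
    "Population allele frequency fit (%s kernel, %d bulk samples; %.0f%% CI)",
    object@kernel, object@nSamples, 100 * object@level))
  if (length(object@fixed))
    cat("fixed:", paste(sprintf("%s = %.4g", names(object@fixed),
                                object@fixed), collapse = ", "), "\n")
})

setMethod("show", "CalibFit", function(object) {
  .showFit(object, sprintf(
    "Known-ratio calibration fit (%d Cq observations, %s likelihood; %.0f%% CI)",
    object@nObs, if (object@paired) "paired" else "unpaired",
    100 * object@level))
})

#' @rdname CqFit-class
#' @param object a fit object.
#' @param ... unused.
#' @export
setMethod("coef", "CqFit", function(object, ...) object@estimate)

#' @rdname CqFit-class
#' @param parm parameter names (default: all).
#' @param level ignored; the level is fixed at fit time.
#' @importFrom stats confint
#' @export
setMethod("confint", "CqFit", function(object, parm, level, ...) {
  ci <- object@ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
})

#' @rdname CqFit-class
#' @importFrom stats logLik
#' @export
setMethod("logLik", "CqFit", function(object, ...) object@loglik)

#' Overall interval-estimation success of a fit
#'
#' \code{TRUE} iff a finite confidence interval was obtained for every free
#' parameter, i.e. the optimizer terminated and every diagonal element of the
#' inverse observed-information matrix was positive. Per-parameter flags are in
#' \code{fitSuccess(fit, each = TRUE)}.
#'
#' @param fit a \linkS4class{FreqFit} or \linkS4class{CalibFit}.
#' @param each if \code{TRUE}, return the named per-parameter logical vector.
#' @return logical.
#' @export
fitSuccess <- function(fit, each = FALSE) {
  stopifnot(is(fit, "CqFit"))
  if (each) fit@paramSuccess else fit@success
}

#' @rdname CqFit-class
#' @param x a fit object.
#' @param row.names,optional conventional; unused.
#' @export
setMethod("as.data.frame", "CqFit",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(parameter = names(x@estimate),
               estimate = unname(x@estimate),
               se_transformed = unname(x@se),
               lower = unname(x@ci[, "lower"]),
               upper = unname(x@ci[, "upper"]),
               ciAvailable = unname(x@paramSuccess),
               row.names = row.names)
  })

## ---------------------------------------------------------------------------
## SimDesign: one parameter region of the numerical experiment
## ---------------------------------------------------------------------------

#' Simulation design for one parameter region
#'
#' Describes one cell of the numerical experiment: a haploid population with R
#' frequency \code{p}, individual DNA yields gamma-distributed with shape
#' \code{k} and mean \code{meanYield} (the scale is derived as
#' \code{meanYield / k}), sampled as \code{nSamples} bulk samples of
#' \code{nPerSample} individuals each, measured under the assay parameters
#' \code{params}.
#'
#' @slot p numeric(1) in [0, 1].
#' @slot k numeric(1) > 0, gamma shape of the individual DNA yield.
#' @slot nPerSample integer(1) >= 1, individuals per bulk sample (n).
#' @slot nSamples integer(1) >= 1, number of bulk samples (N).
#' @slot params a \linkS4class{QpcrParams}.
#' @slot meanYield numeric(1) > 0, mean individual DNA yield relative to the
#'   qPCR threshold.
#' @export
setClass("SimDesign",
  representation(p = "numeric", k = "numeric", nPerSample = "integer",
                 nSamples = "integer", params = "QpcrParams",
                 meanYield = "numeric"))

setValidity("SimDesign", function(object) {
  msg <- character()
  if (!is.finite(object@p) || object@p < 0 || object@p > 1)
    msg <- c(msg, "p must lie in [0, 1]")
  if (!is.finite(object@k) || object@k <= 0)
    msg <- c(msg, "k must be positive")
  if (object@nPerSample < 1L) msg <- c(msg, "nPerSample must be >= 1")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (!is.finite(object@meanYield) || object@meanYield <= 0)
    msg <- c(msg, "meanYield must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SimDesign-class
#' @param p,k,nPerSample,nSamples,params,meanYield see slots.
#' @return A \linkS4class{SimDesign}.
#' @examples
#' SimDesign(p = 0.05, k = 1, nPerSample = 2, nSamples = 8)
#' @export
SimDesign <- function(p, k = 1, nPerSample, nSamples, params = QpcrParams(),
                      meanYield = 1e-6) {
  new("SimDesign", p = as.numeric(p), k = as.numeric(k),
      nPerSample = as.integer(nPerSample), nSamples = as.integer(nSamples),
      params = params, meanYield = as.numeric(meanYield))
}

setMethod("show", "SimDesign", function(object) {
  cat(sprintf(
    "SimDesign: p = %.4g, k = %.3g; %d bulk samples x %d individuals (ntotal = %d)\n",
    object@p, object@k, object@nSamples, object@nPerSample,
    object@nSamples * object@nPerSample))
  cat(sprintf("  mean individual yield %.3g (gamma scale theta = %.3g)\n",
              object@meanYield, object@meanYield / object@k))
})
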