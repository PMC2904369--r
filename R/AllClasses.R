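#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData "colData<-" rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats dnorm pchisq quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' ReciprocalCross: four reciprocal F2 families with markers and a phenotype
#'
#' An S4 container, extending
#' [SummarizedExperiment::SummarizedExperiment-class], for the data of a
#' two-stage reciprocal cross: a `"genotype"` assay of unordered codominant
#' marker genotypes (markers in rows, individuals in columns; integer codes
#' 1 = `11`, 2 = `12`, 3 = `22`, `NA` = missing), `rowData` columns
#' `chromosome` and `position` (cM), and `colData` columns `family` (mating
#' type 1-4, in the order of [iqtlMatingTypes()]) and `phenotype`.
#'
#' Simulated crosses carry the hidden truth (each individual's ordered QTL
#' configuration, the QTL position, the generating effects and residual
#' variance) in `metadata()`.
#'
#' @seealso [makeReciprocalCross()], [readCrossFile()], [simulateCross()]
#' @export
setClass("ReciprocalCross", contains = "SummarizedExperiment")

setValidity("ReciprocalCross", function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("family", "phenotype") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'family' and 'phenotype'")
  else {
    if (!all(cd$family %in% 1:4))
      msg <- c(msg, "'family' must take values in 1:4")
    if (!all(is.finite(cd$phenotype)))
      msg <- c(msg, "every phenotype must be finite")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chromosome", "position") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chromosome' and 'position'")
  else {
    pos <- split(rd$position, rd$chromosome)
    if (!all(vapply(pos, function(p) all(diff(p) > 0), logical(1L))))
      msg <- c(msg, "marker positions must be strictly increasing within chromosomes")
  }
  g <- SummarizedExperiment::assay(object, "genotype")
  if (!all(g %in% c(1L, 2L, 3L, NA)))
    msg <- c(msg, "genotype codes must be 1, 2, 3 or NA")
  for (ph in intersect(c("maternal", "paternal"),
                       SummarizedExperiment::assayNames(object)))
    if (!all(SummarizedExperiment::assay(object, ph) %in% c(1L, 2L, NA)))
      msg <- c(msg, sprintf("'%s' alleles must be 1, 2 or NA", ph))
  if (length(msg)) msg else TRUE
})

#' IQTLFit: a constrained maximum-likelihood fit of the mixture model
#'
#' Result of [emFit()]: the estimated 16 genetic effects (constrained entries
#' exactly zero), the shared residual variance, the maximised observed-data
#' log-likelihood and convergence diagnostics.
#'
#' @slot effects Named numeric vector of the 16 effect estimates.
#' @slot constrained Character vector of effect names fixed at zero.
#' @slot sigma2 Residual variance (squared phenotype units).
#' @slot logLik Observed-data log-likelihood at the optimum.
#' @slot nIter EM iterations used by the winning start.
#' @slot converged Logical convergence flag.
#' @slot logLikTrace Per-iteration log-likelihood of the winning start.
#' @slot nObs Number of individuals.
#' @export
setClass("IQTLFit", representation(
  effects = "numeric", constrained = "character", sigma2 = "numeric",
  logLik = "numeric", nIter = "integer", converged = "logical",
  logLikTrace = "numeric", nObs = "integer"))

setValidity("IQTLFit", function(object) {
  msg <- character()
  if (length(object@effects) != 16L ||
      !identical(names(object@effects), iqtlEffectNames()))
    msg <- c(msg, "effects must be the 16 named genetic effects")
  if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be positive")
  if (!is.finite(object@logLik)) msg <- c(msg, "logLik must be finite")
  if (any(object@effects[object@constrained] != 0))
    msg <- c(msg, "constrained effects must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' IQTLScan: a genome scan for iQTL existence
#'
#' Result of [scanGenome()]: the likelihood-ratio profile over the scan grid,
#' plus (once set) the genome-wide permutation threshold and called peaks.
#'
#' @slot profile `data.frame` with columns `chromosome`, `position`, `lr`,
#'   and the effect estimates at each grid position.
#' @slot step Scan step (cM).
#' @slot threshold Genome-wide LR threshold (`NA` until estimated).
#' @slot alpha Significance level of the threshold.
#' @slot peaks `data.frame` of called peaks (empty until [callPeaks()]).
#' @export
setClass("IQTLScan", representation(
  profile = "data.frame", step = "numeric", threshold = "numeric",
  alpha = "numeric", peaks = "data.frame"))

#' IQTLPowerStudy: replicated simulation study of the test hierarchy
#'
#' Result of [runPowerStudy()]: per-replicate p-values of the requested
#' imprinting tests evaluated at the true QTL position, per-replicate
#' unconstrained effect estimates, and the rejection percentages.
#'
#' @slot scenario Scenario label.
#' @slot n Per-family sample size.
#' @slot h2 Heritability.
#' @slot alpha Nominal level.
#' @slot pvalues reps x tests matrix of p-values.
#' @slot estimates reps x 16 matrix of unconstrained effect estimates.
#' @slot rejection Named percentage of replicates rejecting each test.
#' @slot effects The generating effect vector.
#' @export
setClass("IQTLPowerStudy", representation(
  scenario = "character", n = "integer", h2 = "numeric", alpha = "numeric",
  pvalues = "matrix", estimates = "matrix", rejection = "numeric",
  effects = "numeric"))

#' Accessors for iqtlmap result objects
#'
#' `effectEstimates()` returns the 16 estimated genetic effects of a fit (or
#' the per-replicate estimate matrix of a power study);
#' `residualVariance()` the fitted residual variance; `constrainedEffects()`
#' the names of effects fixed at zero; `scanProfile()` the LR profile of a
#' scan; `rejectionRates()` the per-test rejection percentages of a power
#' study.
#'
#' @param object An [IQTLFit-class], [IQTLScan-class] or
#'   [IQTLPowerStudy-class] object.
#' @return See each generic's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("effectEstimates", function(object) standardGeneric("effectEstimates"))
#' @rdname accessors
#' @export
setGeneric("residualVariance", function(object) standardGeneric("residualVariance"))
#' @rdname accessors
#' @export
setGeneric("constrainedEffects", function(object) standardGeneric("constrainedEffects"))
#' @rdname accessors
#' @export
setGeneric("scanProfile", function(object) standardGeneric("scanProfile"))
#' @rdname accessors
#' @export
setGeneric("rejectionRates", function(object) standardGeneric("rejectionRates"))

#' @rdname accessors
#' @export
setMethod("effectEstimates", "IQTLFit", function(object) object@effects)
#' @rdname accessors
#' @export
setMethod("effectEstimates", "IQTLPowerStudy", function(object) object@estimates)
#' @rdname accessors
#' @export
setMethod("residualVariance", "IQTLFit", function(object) object@sigma2)
#' @rdname accessors
#' @export
setMethod("constrainedEffects", "IQTLFit", function(object) object@constrained)
#' @rdname accessors
#' @export
setMethod("scanProfile", "IQTLScan", function(object) object@profile)
#' @rdname accessors
#' @export
setMethod("rejectionRates", "IQTLPowerStudy", function(object) object@rejection)

#' @describeIn IQTLFit Log-likelihood of the fitted mixture model.
#' @param object,... See [stats::logLik()].
#' @export
setMethod("logLik", "IQTLFit", function(object, ...) {
  ll <- object@logLik
  attr(ll, "df") <- 17L - length(object@constrained)  # free effects + sigma2
  attr(ll, "nobs") <- object@nObs
  class(ll) <- "logLik"
  ll
})

setMethod("show", "IQTLFit", function(object) {
  cat("IQTLFit:", 16L - length(object@constrained), "free effects")
  if (length(object@constrained))
    cat(" (constrained: ", paste(object@constrained, collapse = ", "), ")",
        sep = "")
  cat("\n  logLik:", format(object@logLik, digits = 6),
      " sigma2:", format(object@sigma2, digits = 4),
      " iterations:", object@nIter,
      if (!object@converged) " [not converged]" else "", "\n")
  print(round(object@effects, 4))
})

setMethod("show", "IQTLScan", function(object) {
  cat("IQTLScan:", nrow(object@profile), "positions on",
      length(unique(object@profile$chromosome)), "chromosome(s), step",
      object@step, "cM\n")
  cat("  max LR:", format(max(object@profile$lr), digits = 4))
  if (is.finite(object@threshold))
    cat("  threshold (alpha = ", object@alpha, "): ",
        format(object@threshold, digits = 4), sep = "")
  cat("\n")
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks)
  }
})

setMethod("show", "IQTLPowerStudy", function(object) {
  cat("IQTLPowerStudy: scenario", object@scenario,
      " n =", object@n, "/family, h2 =", object@h2,
      ",", nrow(object@pvalues), "replicates, alpha =", object@alpha, "\n")
  cat("  rejection (%):\n")
  print(object@rejection)
})
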