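## S4 classes for the package's central containers. Trees are ape "phylo"
## objects (the de-facto standard container for comparative methods) and are
## validated by validatePhylo() rather than wrapped.

#' PipelineConfig: every stated analysis threshold in one object
#'
#' Houses the constants the pipeline applies: the dominance threshold on the
#' venom phenotype, amplicon QC bounds, the subsampling depth, the variant
#' abundance/prevalence rule, the transcriptomic variant retention rule, the
#' qPCR triplicate tolerance and calibrator definition, the bootstrap size,
#' and the default random seed.
#'
#' @slot dominanceThreshold fraction of total toxin expression a family must
#'   strictly exceed to be called dominant (default 0.5).
#' @slot ampliconMinLength,ampliconMaxLength inclusive amplicon length bounds
#'   in bp (defaults 300 and 500).
#' @slot subsampleDepth number of reads drawn per sample (default 14800).
#' @slot variantMinAbundance minimum within-sample read count for a variant
#'   (default 100).
#' @slot variantMinIndividuals minimum number of individuals carrying a
#'   variant (default 2).
#' @slot retentionFraction cumulative-abundance fraction for transcriptomic
#'   variant retention (default 0.70).
#' @slot minIdenticalCopies identical-copy count that alone retains a
#'   transcriptomic variant (default 10).
#' @slot cqTolerance maximum pairwise Cq deviation inside a qPCR triplicate
#'   (default 0.2 cycles).
#' @slot calibratorCopies diploid copy number assigned to the reference
#'   calibrator (default 1).
#' @slot bootstrapReplicates parametric bootstrap size (default 1000).
#' @slot seed default random seed.
#' @export
setClass("PipelineConfig",
  representation(
    dominanceThreshold = "numeric",
    ampliconMinLength = "integer",
    ampliconMaxLength = "integer",
    subsampleDepth = "integer",
    variantMinAbundance = "integer",
    variantMinIndividuals = "integer",
    retentionFraction = "numeric",
    minIdenticalCopies = "integer",
    cqTolerance = "numeric",
    calibratorCopies = "numeric",
    bootstrapReplicates = "integer",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  errs <- character(0)
  pos <- c(
    dominanceThreshold = object@dominanceThreshold,
    ampliconMinLength = object@ampliconMinLength,
    ampliconMaxLength = object@ampliconMaxLength,
    subsampleDepth = object@subsampleDepth,
    variantMinAbundance = object@variantMinAbundance,
    variantMinIndividuals = object@variantMinIndividuals,
    retentionFraction = object@retentionFraction,
    minIdenticalCopies = object@minIdenticalCopies,
    cqTolerance = object@cqTolerance,
    calibratorCopies = object@calibratorCopies,
    bootstrapReplicates = object@bootstrapReplicates
  )
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    errs <- c(errs, "all thresholds must be strictly positive and finite")
  }
  for (f in c("dominanceThreshold", "retentionFraction")) {
    v <- slot(object, f)
    if (length(v) != 1L || v <= 0 || v > 1) {
      errs <- c(errs, sprintf("%s must lie in (0, 1]", f))
    }
  }
  if (object@ampliconMinLength > object@ampliconMaxLength) {
    errs <- c(errs, "ampliconMinLength must not exceed ampliconMaxLength")
  }
  if (length(errs)) errs else TRUE
})

#' FamilyComposition: the venom expression phenotype
#'
#' Per-sample cumulative TPM and fractional contribution of each toxin
#' family. Samples whose total annotated TPM is zero are flagged undefined
#' and carry `NA` fractions.
#'
#' @slot tpm numeric matrix, samples x families, cumulative TPM.
#' @slot fraction numeric matrix, samples x families; rows sum to 1 for
#'   defined samples, all-`NA` otherwise.
#' @slot defined logical per sample, `FALSE` when total annotated TPM is 0.
#' @export
setClass("FamilyComposition",
  representation(tpm = "matrix", fraction = "matrix", defined = "logical")
)

setValidity("FamilyComposition", function(object) {
  errs <- character(0)
  if (!identical(dim(object@tpm), dim(object@fraction))) {
    errs <- c(errs, "tpm and fraction must have identical dimensions")
  }
  if (length(object@defined) != nrow(object@tpm)) {
    errs <- c(errs, "defined must have one entry per sample")
  }
  if (any(object@tpm < 0, na.rm = TRUE)) {
    errs <- c(errs, "cumulative TPM must be nonnegative")
  }
  fr <- object@fraction[object@defined, , drop = FALSE]
  if (nrow(fr)) {
    if (any(!is.finite(fr)) || any(fr < -1e-12) || any(fr > 1 + 1e-12)) {
      errs <- c(errs, "fractions of defined samples must lie in [0, 1]")
    } else if (any(abs(rowSums(fr) - 1) > 1e-9)) {
      errs <- c(errs, "fractions of defined samples must sum to 1 (tol 1e-9)")
    }
  }
  if (length(errs)) errs else TRUE
})

#' ModelFit: one evolutionary model fitted to one trait
#'
#' @slot model one of "BM", "OU", "EB", "JN".
#' @slot params named numeric vector of fitted parameters on their natural
#'   scale (e.g. `sigma2`, `root`; plus `alpha`/`theta` for OU, `r` for EB,
#'   `lambdaJ`/`delta2` for JN).
#' @slot logLik maximized log-likelihood.
#' @slot k number of free parameters.
#' @slot AIC `2 k - 2 logLik`.
#' @slot weight AIC weight relative to a compared set (`NA` until
#'   [aicWeights()] is applied).
#' @slot convergence optimizer convergence code (0 = converged).
#' @export
setClass("ModelFit",
  representation(model = "character", params = "numeric", logLik = "numeric",
                 k = "numeric", AIC = "numeric", weight = "numeric",
                 convergence = "numeric")
)

setValidity("ModelFit", function(object) {
  errs <- character(0)
  if (!object@model %in% c("BM", "OU", "EB", "JN")) {
    errs <- c(errs, "model must be one of BM, OU, EB, JN")
  }
  if (is.finite(object@logLik) &&
      abs(object@AIC - (2 * object@k - 2 * object@logLik)) > 1e-6) {
    errs <- c(errs, "AIC must equal 2k - 2 logLik")
  }
  if (length(errs)) errs else TRUE
})

#' PhyloCovarianceResult: multivariate evolutionary covariance with bootstrap
#'
#' @slot cov p x p evolutionary trait covariance (trait^2 per unit time).
#' @slot rootMean length-p maximum-likelihood root mean vector.
#' @slot lower,upper p x p percentile 95% bootstrap bounds.
#' @slot significant logical p x p; off-diagonal entry is `TRUE` when the
#'   bootstrap interval excludes 0.
#' @slot B number of bootstrap replicates.
#' @slot seed seed used for the bootstrap.
#' @export
setClass("PhyloCovarianceResult",
  representation(cov = "matrix", rootMean = "numeric", lower = "matrix",
                 upper = "matrix", significant = "matrix", B = "integer",
                 seed = "integer")
)

setValidity("PhyloCovarianceResult", function(object) {
  errs <- character(0)
  p <- nrow(object@cov)
  if (ncol(object@cov) != p) errs <- c(errs, "cov must be square")
  if (max(abs(object@cov - t(object@cov))) > 1e-8) {
    errs <- c(errs, "cov must be symmetric")
  }
  ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    errs <- c(errs, "cov must be positive semi-definite")
  }
  if (length(object@rootMean) != p) {
    errs <- c(errs, "rootMean length must match cov dimension")
  }
  if (length(errs)) errs else TRUE
})

#' HaplotypeArray: an ordered toxin-copy array for one locus haplotype
#'
#' Loci are stored 0-based half-open (BED convention) with strand "+"/"-",
#' sorted by start and non-overlapping; intergenic gaps are derived.
#'
#' @slot haplotype haplotype identifier.
#' @slot loci data.frame with columns `label` (character), `strand`
#'   ("+"/"-"), `start`, `end` (integer bp, 0-based half-open), `pseudogene`
#'   (logical).
#' @export
setClass("HaplotypeArray",
  representation(haplotype = "character", loci = "data.frame")
)

setValidity("HaplotypeArray", function(object) {
  errs <- character(0)
  df <- object@loci
  need <- c("label", "strand", "start", "end", "pseudogene")
  if (!all(need %in% names(df))) {
    return(sprintf("loci must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(df)) {
    if (any(df$end <= df$start)) errs <- c(errs, "each locus must have end > start")
    if (is.unsorted(df$start, strictly = FALSE)) {
      errs <- c(errs, "loci must be sorted by start")
    }
    if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
      errs <- c(errs, "loci must not overlap")
    }
    if (!all(df$strand %in% c("+", "-"))) {
      errs <- c(errs, "strand must be '+' or '-'")
    }
  }
  if (length(errs)) errs else TRUE
})

#' EfficiencyFit: qPCR assay efficiency from a dilution series
#'
#' @slot gene assay/gene name.
#' @slot slope OLS slope of Cq on log10(input mass).
#' @slot efficiency `10^(-1/slope) - 1` (fraction; 1 = perfect doubling).
#' @slot accepted `TRUE` when efficiency lies in \[0.90, 1.10\].
#' @export
setClass("EfficiencyFit",
  representation(gene = "character", slope = "numeric",
                 efficiency = "numeric", accepted = "logical")
)

## ---- show methods ---------------------------------------------------------

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  dominance threshold : %.3g\n", object@dominanceThreshold))
  cat(sprintf("  amplicon length     : [%d, %d] bp\n",
              object@ampliconMinLength, object@ampliconMaxLength))
  cat(sprintf("  subsample depth     : %d reads\n", object@subsampleDepth))
  cat(sprintf("  variant rule        : count >= %d in >= %d individuals\n",
              object@variantMinAbundance, object@variantMinIndividuals))
  cat(sprintf("  retention rule      : %.0f%% prefix or >= %d copies\n",
              100 * object@retentionFraction, object@minIdenticalCopies))
  cat(sprintf("  Cq tolerance        : %.2g cycles\n", object@cqTolerance))
  cat(sprintf("  calibrator copies   : %g\n", object@calibratorCopies))
  cat(sprintf("  bootstrap B         : %d, seed %d\n",
              object@bootstrapReplicates, object@seed))
})

setMethod("show", "FamilyComposition", function(object) {
  cat(sprintf("FamilyComposition: %d samples x %d families (%d undefined)\n",
              nrow(object@tpm), ncol(object@tpm), sum(!object@defined)))
  n <- min(nrow(object@fraction), 5L)
  if (n) print(round(object@fraction[seq_len(n), , drop = FALSE], 3))
  if (nrow(object@fraction) > n) cat("  ...\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s]: logLik = %.4f, k = %d, AIC = %.4f%s\n",
              object@model, object@logLik, as.integer(object@k), object@AIC,
              if (is.finite(object@weight))
                sprintf(", weight = %.4f", object@weight) else ""))
  print(signif(object@params, 6))
})

setMethod("show", "PhyloCovarianceResult", function(object) {
  cat(sprintf("PhyloCovarianceResult: %d traits, B = %d bootstrap replicates\n",
              nrow(object@cov), object@B))
  cat("Evolutionary covariance (R-hat):\n")
  print(signif(object@cov, 4))
  off <- object@significant & upper.tri(object@significant)
  cat(sprintf("Significant off-diagonal pairs: %d\n", sum(off)))
})

setMethod("show", "HaplotypeArray", function(object) {
  cat(sprintf("HaplotypeArray '%s': %d loci (%d pseudogenes)\n",
              object@haplotype, nrow(object@loci), sum(object@loci$pseudogene)))
  if (nrow(object@loci)) {
    cat("  labels:", paste(object@loci$label, collapse = " "), "\n")
  }
})

setMethod("show", "EfficiencyFit", function(object) {
  cat(sprintf("EfficiencyFit [%s]: slope = %.4f, efficiency = %.1f%% (%s)\n",
              object@gene, object@slope, 100 * object@efficiency,
              if (object@accepted) "accepted" else "rejected"))
})
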