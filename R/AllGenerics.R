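## Generics and accessors. Slot access from user code goes through these.

#' @rdname FamilyComposition-class
#' @param object a `FamilyComposition`.
#' @export
setGeneric("compositionTPM", function(object) standardGeneric("compositionTPM"))

#' @rdname FamilyComposition-class
#' @export
setGeneric("compositionFractions",
           function(object) standardGeneric("compositionFractions"))

#' @rdname FamilyComposition-class
#' @export
setGeneric("isDefined", function(object) standardGeneric("isDefined"))

#' @rdname FamilyComposition-class
setMethod("compositionTPM", "FamilyComposition", function(object) object@tpm)

#' @rdname FamilyComposition-class
setMethod("compositionFractions", "FamilyComposition",
          function(object) object@fraction)

#' @rdname FamilyComposition-class
setMethod("isDefined", "FamilyComposition",
          function(object) setNames(object@defined, rownames(object@tpm)))

#' @rdname ModelFit-class
#' @param object a `ModelFit`.
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname ModelFit-class
setMethod("modelParams", "ModelFit", function(object) object@params)

#' @rdname ModelFit-class
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname ModelFit-class
setMethod("modelName", "ModelFit", function(object) object@model)

#' @rdname ModelFit-class
#' @export
setGeneric("aicWeight", function(object) standardGeneric("aicWeight"))

#' @rdname ModelFit-class
setMethod("aicWeight", "ModelFit", function(object) object@weight)

#' Log-likelihood of a ModelFit
#' @param object a `ModelFit`.
#' @param ... unused.
#' @export
setMethod("logLik", "ModelFit", function(object, ...) {
  structure(object@logLik, df = object@k, class = "logLik")
})

#' AIC of a ModelFit
#' @param object a `ModelFit`.
#' @param ... unused.
#' @param k unused (fixed at 2 per parameter).
#' @export
setMethod("AIC", "ModelFit", function(object, ..., k = 2) object@AIC)

#' @rdname PhyloCovarianceResult-class
#' @param object a `PhyloCovarianceResult`.
#' @export
setGeneric("covMatrix", function(object) standardGeneric("covMatrix"))

#' @rdname PhyloCovarianceResult-class
setMethod("covMatrix", "PhyloCovarianceResult", function(object) object@cov)

#' @rdname PhyloCovarianceResult-class
#' @export
setGeneric("rootMean", function(object) standardGeneric("rootMean"))

#' @rdname PhyloCovarianceResult-class
setMethod("rootMean", "PhyloCovarianceResult", function(object) object@rootMean)

#' @rdname PhyloCovarianceResult-class
#' @export
setGeneric("significantPairs",
           function(object) standardGeneric("significantPairs"))

#' @rdname PhyloCovarianceResult-class
setMethod("significantPairs", "PhyloCovarianceResult",
          function(object) object@significant)

#' @rdname HaplotypeArray-class
#' @param object a `HaplotypeArray`.
#' @export
setGeneric("lociTable", function(object) standardGeneric("lociTable"))

#' @rdname HaplotypeArray-class
setMethod("lociTable", "HaplotypeArray", function(object) object@loci)

#' @rdname HaplotypeArray-class
#' @export
setGeneric("intergenicGaps", function(object) standardGeneric("intergenicGaps"))

#' @rdname HaplotypeArray-class
setMethod("intergenicGaps", "HaplotypeArray", function(object) {
  df <- object@loci
  if (nrow(df) < 2) return(numeric(0))
  df$start[-1] - df$end[-nrow(df)]
})

#' @rdname HaplotypeArray-class
#' @export
setGeneric("haplotypeLabels", function(object) standardGeneric("haplotypeLabels"))

#' @rdname HaplotypeArray-class
setMethod("haplotypeLabels", "HaplotypeArray",
          function(object) object@loci$label)
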