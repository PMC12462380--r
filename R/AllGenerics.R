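#' @importFrom Biostrings alphabet
NULL

#' Accessors for SubstModelKit classes
#'
#' \code{modelName} returns the identifier, \code{alphabet} the ordered symbol
#' set (reusing the Biostrings generic), \code{exchangeabilities} the symmetric
#' relative-rate matrix M, \code{equilibriumFreqs} the frequency vector f, and
#' \code{isFrequencyFree} whether a uniform default was substituted for absent
#' frequencies. \code{probMatrix} extracts P from a
#' \linkS4class{TransitionMatrix}, \code{generator} extracts Q.
#'
#' @param x an object of the relevant class.
#' @param ... unused.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setGeneric("exchangeabilities", function(x) standardGeneric("exchangeabilities"))
#' @rdname accessors
#' @export
setGeneric("equilibriumFreqs", function(x) standardGeneric("equilibriumFreqs"))
#' @rdname accessors
#' @export
setGeneric("isFrequencyFree", function(x) standardGeneric("isFrequencyFree"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("generator", function(x) standardGeneric("generator"))
#' @rdname accessors
#' @export
setGeneric("stationaryDist", function(x) standardGeneric("stationaryDist"))
#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

setMethod("modelName", "RateModel", function(x) x@name)
setMethod("modelName", "ScoreModel", function(x) x@name)
setMethod("modelName", "ModelRecord", function(x) modelName(x@model))

#' @rdname accessors
#' @export
setMethod("alphabet", "RateModel", function(x, ...) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "ScoreModel", function(x, ...) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "GeneratorMatrix", function(x, ...) x@alphabet)

setMethod("exchangeabilities", "RateModel", function(x) x@M)
setMethod("equilibriumFreqs", "RateModel", function(x) x@f)
setMethod("isFrequencyFree", "RateModel", function(x) x@freqFree)
setMethod("scoreMatrix", "ScoreModel", function(x) x@S)
setMethod("generator", "GeneratorMatrix", function(x) x@Q)
setMethod("stationaryDist", "GeneratorMatrix", function(x) x@pi)
setMethod("probMatrix", "TransitionMatrix", function(x) x@P)
setMethod("distances", "ModelDistanceMatrix", function(x) {
  d <- x@D
  dimnames(d) <- list(x@labels, x@labels)
  d
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel '%s': %d states [%s]%s\n", object@name,
              length(object@alphabet),
              paste(head(object@alphabet, 6), collapse = ""),
              if (object@freqFree) " (uniform default frequencies)" else ""))
  cat(sprintf("  max relative rate %.4g; frequency range [%.4g, %.4g]\n",
              max(object@M), min(object@f), max(object@f)))
})

setMethod("show", "ScoreModel", function(object) {
  cat(sprintf("ScoreModel '%s': %d states, scores in [%g, %g]\n", object@name,
              length(object@alphabet), min(object@S), max(object@S)))
})

setMethod("show", "ModelRecord", function(object) {
  cat(sprintf("ModelRecord '%s' (%s, %s, %d)\n", modelName(object),
              object@kind, object@taxonomicGroup, object@year))
})

setMethod("show", "GeneratorMatrix", function(object) {
  cat(sprintf("GeneratorMatrix: %d states, %s; mean rate at stationarity %.6g\n",
              length(object@alphabet),
              if (object@scaled) "scaled (expected 1 substitution/site)" else "unscaled",
              -sum(object@pi * diag(object@Q))))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix P(t = %g): %d states\n", object@t, nrow(object@P)))
})

setMethod("show", "RateHeterogeneity", function(object) {
  cat(sprintf("RateHeterogeneity: %d categories%s%s\n", length(object@rates),
              if (!is.na(object@alpha)) sprintf(", gamma alpha = %g (k = %d)", object@alpha, object@k) else "",
              if (object@pInv > 0) sprintf(", pInv = %g", object@pInv) else ""))
  cat("  rates:", paste(sprintf("%.4g", object@rates), collapse = " "), "\n")
})

setMethod("show", "ModelDistanceMatrix", function(object) {
  cat(sprintf("ModelDistanceMatrix (%s): %d models, max distance %.4g\n",
              object@mode, length(object@labels), max(object@D)))
})

setMethod("show", "CandidateSpec", function(object) {
  cat(candidateName(object), "\n")
})

#' Display name of a candidate ("model", "model+G", "model+I+G", ...)
#'
#' @param x a \linkS4class{CandidateSpec}.
#' @return Character scalar.
#' @export
candidateName <- function(x) {
  paste0(modelName(x@model), if (x@useInv) "+I" else "", if (x@useGamma) "+G" else "")
}
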