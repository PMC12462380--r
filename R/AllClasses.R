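#' @import methods
#' @importFrom stats optimize pgamma qgamma rexp rgamma rlnorm rnorm runif
#' @importFrom utils read.delim write.table head
NULL

## ---------------------------------------------------------------------------
## RateModel: symmetric relative-rate matrix M plus equilibrium frequencies f
## ---------------------------------------------------------------------------

#' RateModel: an empirical substitution model
#'
#' Holds the two components of a time-reversible empirical substitution model:
#' the symmetric matrix \code{M} of relative rates of change between residue
#' pairs and the vector \code{f} of equilibrium frequencies. The alphabet
#' defaults to the 20 amino acids in PAML order but any alphabet with at least
#' two symbols is allowed, so small toy models can exercise every algorithm.
#'
#' Invariants enforced by the validity method: \code{M} symmetric with zero
#' diagonal and nonnegative entries, at least one positive entry; \code{f}
#' nonnegative and summing to 1 within 1e-6.
#'
#' @slot name identifier string.
#' @slot alphabet ordered character vector of residue symbols.
#' @slot M symmetric numeric matrix of relative rates (zero diagonal).
#' @slot f numeric vector of equilibrium frequencies.
#' @slot freqFree TRUE when the source file carried no frequencies and the
#'   uniform default was substituted.
#' @export
setClass("RateModel",
  representation(name = "character", alphabet = "character",
                 M = "matrix", f = "numeric", freqFree = "logical"),
  prototype(name = "model", freqFree = FALSE))

setValidity("RateModel", function(object) {
  n <- length(object@alphabet)
  M <- object@M
  msg <- character()
  if (n < 2L) msg <- c(msg, "alphabet must have at least 2 symbols")
  if (anyDuplicated(object@alphabet)) msg <- c(msg, "alphabet symbols must be unique")
  if (!all(dim(M) == c(n, n))) msg <- c(msg, "M must be n x n for an n-symbol alphabet")
  if (length(object@f) != n) msg <- c(msg, "f must have one entry per symbol")
  if (length(msg)) return(msg)
  tol <- 1e-12 * max(1, max(abs(M)))
  if (max(abs(M - t(M))) > tol) msg <- c(msg, "M must be symmetric")
  if (any(diag(M) != 0)) msg <- c(msg, "M must have a zero diagonal")
  if (any(M < 0)) msg <- c(msg, "M entries must be nonnegative")
  if (max(M) <= 0) msg <- c(msg, "M must have at least one positive entry")
  if (any(object@f < 0)) msg <- c(msg, "frequencies must be nonnegative")
  if (abs(sum(object@f) - 1) > 1e-6) msg <- c(msg, "frequencies must sum to 1 (tol 1e-6)")
  if (length(msg)) msg else TRUE
})

#' Construct a RateModel
#'
#' @param M symmetric relative-rate matrix with zero diagonal. A lower- or
#'   upper-triangular input is symmetrized automatically.
#' @param f equilibrium frequencies (one per symbol). Defaults to uniform, in
#'   which case the model is flagged frequency-free.
#' @param alphabet residue symbols; defaults to \code{aminoAcids()} for 20-row
#'   input or to the dimnames of \code{M}.
#' @param name model identifier.
#' @param freqFree set by the parser when frequencies were absent from a file.
#' @return A validated \linkS4class{RateModel}.
#' @export
#' @examples
#' m <- matrix(1, 3, 3); diag(m) <- 0
#' RateModel(m, c(0.5, 0.3, 0.2), alphabet = c("a", "b", "c"), name = "toy")
RateModel <- function(M, f = NULL, alphabet = NULL, name = "model", freqFree = NULL) {
  M <- as.matrix(M)
  if (is.null(alphabet)) {
    alphabet <- if (!is.null(rownames(M))) rownames(M)
      else if (nrow(M) == 20L) aminoAcids()
      else .stopf("alphabet must be given when M is %d x %d and unnamed", nrow(M), ncol(M))
  }
  if (all(M[upper.tri(M)] == 0) && any(M[lower.tri(M)] > 0)) M <- M + t(M)
  else if (all(M[lower.tri(M)] == 0) && any(M[upper.tri(M)] > 0)) M <- M + t(M)
  if (is.null(freqFree)) freqFree <- is.null(f)
  if (is.null(f)) f <- rep(1 / nrow(M), nrow(M))
  dimnames(M) <- list(alphabet, alphabet)
  new("RateModel", name = name, alphabet = as.character(alphabet),
      M = M, f = unname(as.numeric(f)), freqFree = freqFree)
}

## ---------------------------------------------------------------------------
## ScoreModel
## ---------------------------------------------------------------------------

#' ScoreModel: a substitution score matrix
#'
#' Symmetric matrix of substitution scores (log-odds style), as used by
#' sequence-alignment methods. Unlike \linkS4class{RateModel}, entries may be
#' negative and the diagonal may be nonzero.
#'
#' @slot name identifier string.
#' @slot alphabet ordered residue symbols.
#' @slot S symmetric numeric score matrix.
#' @export
setClass("ScoreModel",
  representation(name = "character", alphabet = "character", S = "matrix"))

setValidity("ScoreModel", function(object) {
  n <- length(object@alphabet)
  if (!all(dim(object@S) == c(n, n))) return("S must be n x n")
  if (!identical(object@S, t(object@S))) return("S must be exactly symmetric")
  TRUE
})

#' @rdname ScoreModel-class
#' @param S symmetric score matrix.
#' @param alphabet,name see \linkS4class{RateModel}.
#' @export
ScoreModel <- function(S, alphabet = NULL, name = "score") {
  S <- as.matrix(S)
  if (is.null(alphabet)) {
    alphabet <- if (!is.null(rownames(S))) rownames(S)
      else if (nrow(S) == 20L) aminoAcids()
      else .stopf("alphabet must be given for a %d-symbol score matrix", nrow(S))
  }
  dimnames(S) <- list(alphabet, alphabet)
  new("ScoreModel", name = name, alphabet = as.character(alphabet), S = S)
}

## ---------------------------------------------------------------------------
## ModelRecord: a model plus catalog metadata
## ---------------------------------------------------------------------------

.taxonomicGroups <- c("nuclear_general", "nuclear_taxon_specific",
                      "mitochondrial", "chloroplast", "viral", "other")

#' ModelRecord: catalog entry for a substitution model
#'
#' Couples a \linkS4class{RateModel} or \linkS4class{ScoreModel} with the
#' metadata the catalog filters on: matrix kind, taxonomic group, publication
#' year, authors, reference and free-text comments.
#'
#' @slot model the model payload.
#' @slot kind \code{"rate"} or \code{"score"}, consistent with the payload.
#' @slot taxonomicGroup one of nuclear_general, nuclear_taxon_specific,
#'   mitochondrial, chloroplast, viral, other.
#' @slot year publication year (> 1960).
#' @slot authors,reference,comments free-text metadata.
#' @export
setClass("ModelRecord",
  representation(model = "ANY", kind = "character", taxonomicGroup = "character",
                 year = "integer", authors = "character",
                 reference = "character", comments = "character"))

setValidity("ModelRecord", function(object) {
  msg <- character()
  if (!object@kind %in% c("rate", "score")) msg <- c(msg, "kind must be 'rate' or 'score'")
  ok <- (object@kind == "rate" && is(object@model, "RateModel")) ||
        (object@kind == "score" && is(object@model, "ScoreModel"))
  if (!ok) msg <- c(msg, "kind inconsistent with the model payload")
  if (!object@taxonomicGroup %in% .taxonomicGroups)
    msg <- c(msg, paste("taxonomicGroup must be one of:", paste(.taxonomicGroups, collapse = ", ")))
  if (object@year <= 1960L) msg <- c(msg, "year must be > 1960")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelRecord-class
#' @param model a RateModel or ScoreModel.
#' @param kind "rate" or "score"; inferred from the payload class by default.
#' @param taxonomicGroup,year,authors,reference,comments catalog metadata.
#' @export
ModelRecord <- function(model, kind = NULL, taxonomicGroup = "other",
                        year = 2000L, authors = "", reference = "", comments = "") {
  if (is.null(kind)) kind <- if (is(model, "ScoreModel")) "score" else "rate"
  new("ModelRecord", model = model, kind = kind, taxonomicGroup = taxonomicGroup,
      year = as.integer(year), authors = authors, reference = reference,
      comments = comments)
}

## ---------------------------------------------------------------------------
## GeneratorMatrix and TransitionMatrix
## ---------------------------------------------------------------------------

#' GeneratorMatrix: normalized instantaneous-rate matrix
#'
#' The generator Q of the substitution CTMC, with off-diagonal entries
#' \code{Q[i,j] = M[i,j] * f[j]} and the diagonal set so rows sum to zero.
#' When \code{scaled} the matrix is divided by the expected rate at
#' stationarity so branch lengths are expected substitutions per site.
#' Detailed balance \code{pi[i] Q[i,j] == pi[j] Q[j,i]} holds by construction.
#'
#' @slot Q square numeric matrix, zero row sums.
#' @slot pi stationary distribution (equal to the model's \code{f}).
#' @slot alphabet residue symbols.
#' @slot scaled TRUE when the expected rate at stationarity is 1.
#' @export
setClass("GeneratorMatrix",
  representation(Q = "matrix", pi = "numeric", alphabet = "character",
                 scaled = "logical"))

setValidity("GeneratorMatrix", function(object) {
  Q <- object@Q; p <- object@pi
  msg <- character()
  if (length(p) != nrow(Q)) return("pi must match the dimension of Q")
  if (max(abs(rowSums(Q))) > 1e-10) msg <- c(msg, "rows of Q must sum to 0 (tol 1e-10)")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) msg <- c(msg, "off-diagonal entries of Q must be nonnegative")
  db <- p * Q - t(p * Q)
  if (max(abs(db)) > 1e-10) msg <- c(msg, "detailed balance pi_i Q_ij = pi_j Q_ji violated")
  if (object@scaled && abs(-sum(p * diag(Q)) - 1) > 1e-10)
    msg <- c(msg, "scaled generator must have expected rate 1")
  if (length(msg)) msg else TRUE
})

#' TransitionMatrix: substitution probabilities over a branch
#'
#' \code{P(t) = exp(Q t)}: row \code{i} gives the probability of each end
#' state after evolving for branch length \code{t} from state \code{i}.
#'
#' @slot P square stochastic matrix (rows sum to 1, entries in [0, 1]).
#' @slot t branch length in expected substitutions per site.
#' @slot alphabet residue symbols.
#' @export
setClass("TransitionMatrix",
  representation(P = "matrix", t = "numeric", alphabet = "character"))

setValidity("TransitionMatrix", function(object) {
  P <- object@P
  msg <- character()
  if (any(P < 0) || any(P > 1)) msg <- c(msg, "entries of P must lie in [0, 1]")
  if (max(abs(rowSums(P) - 1)) > 1e-10) msg <- c(msg, "rows of P must sum to 1 (tol 1e-10)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RateHeterogeneity
## ---------------------------------------------------------------------------

#' RateHeterogeneity: among-site rate variation (+G / +I)
#'
#' Discrete description of among-site rate variation: \code{k} gamma
#' categories (equal probability, category-mean rates) from shape
#' \code{alpha}, optionally augmented with an invariable-site category of rate
#' zero and probability \code{pInv}. The category rates are normalized so the
#' expected rate over all sites is 1, keeping branch lengths in expected
#' substitutions per site.
#'
#' @slot pInv proportion of invariable sites in [0, 1].
#' @slot alpha gamma shape (NA for no gamma component).
#' @slot k number of discrete gamma categories.
#' @slot rates per-category rates (including the zero-rate invariant category
#'   when present).
#' @slot probs per-category probabilities, summing to 1.
#' @export
setClass("RateHeterogeneity",
  representation(pInv = "numeric", alpha = "numeric", k = "integer",
                 rates = "numeric", probs = "numeric"))

setValidity("RateHeterogeneity", function(object) {
  msg <- character()
  if (object@pInv < 0 || object@pInv > 1) msg <- c(msg, "pInv must lie in [0, 1]")
  if (length(object@rates) != length(object@probs))
    return("rates and probs must have equal length")
  if (any(object@rates < 0)) msg <- c(msg, "category rates must be nonnegative")
  if (abs(sum(object@probs) - 1) > 1e-10) msg <- c(msg, "category probabilities must sum to 1")
  if (object@pInv < 1 && abs(sum(object@probs * object@rates) - 1) > 1e-9)
    msg <- c(msg, "expected rate over sites must be 1")
  if (length(msg)) msg else TRUE
})

#' Homogeneous (single-rate) site model
#'
#' @return A \linkS4class{RateHeterogeneity} with one category of rate 1:
#'   no gamma variation and no invariable sites.
#' @export
homogeneousRates <- function() {
  new("RateHeterogeneity", pInv = 0, alpha = NA_real_, k = 1L, rates = 1, probs = 1)
}

## ---------------------------------------------------------------------------
## ModelDistanceMatrix
## ---------------------------------------------------------------------------

#' ModelDistanceMatrix: pairwise distances between substitution models
#'
#' Symmetric nonnegative matrix of mean-absolute-difference distances between
#' models, computed on normalized relative rates (\code{"rates"}), equilibrium
#' frequencies (\code{"freqs"}), or their equal-contribution average
#' (\code{"combined"}).
#'
#' @slot labels model names.
#' @slot D symmetric nonnegative matrix with zero diagonal.
#' @slot mode one of "rates", "freqs", "combined".
#' @export
setClass("ModelDistanceMatrix",
  representation(labels = "character", D = "matrix", mode = "character"))

setValidity("ModelDistanceMatrix", function(object) {
  D <- object@D
  msg <- character()
  if (!all(dim(D) == length(object@labels))) return("D must be square on labels")
  if (!object@mode %in% c("rates", "freqs", "combined"))
    msg <- c(msg, "mode must be rates, freqs or combined")
  if (max(abs(D - t(D))) > 1e-12) msg <- c(msg, "D must be symmetric")
  if (any(diag(D) != 0)) msg <- c(msg, "diagonal of D must be zero")
  if (any(D < 0)) msg <- c(msg, "distances must be nonnegative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CandidateSpec
## ---------------------------------------------------------------------------

#' CandidateSpec: one entry of a model-selection candidate set
#'
#' A substitution model together with flags for the +G (discrete gamma) and
#' +I (invariable sites) extensions, as in candidate names like "WAG+I+G".
#'
#' @slot model the \linkS4class{RateModel}.
#' @slot useGamma fit a discrete-gamma shape parameter.
#' @slot useInv fit a proportion of invariable sites.
#' @slot k gamma category count.
#' @export
setClass("CandidateSpec",
  representation(model = "RateModel", useGamma = "logical",
                 useInv = "logical", k = "integer"))

setValidity("CandidateSpec", function(object) {
  if (object@useGamma && object@k < 1L) return("k must be >= 1 when useGamma")
  TRUE
})

#' @rdname CandidateSpec-class
#' @param model a RateModel.
#' @param gamma,inv logical flags for the +G and +I components.
#' @param k gamma category count (default 4).
#' @export
candidateSpec <- function(model, gamma = FALSE, inv = FALSE, k = 4L) {
  new("CandidateSpec", model = model, useGamma = gamma, useInv = inv,
      k = as.integer(k))
}
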