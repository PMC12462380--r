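## CTMC machinery: generator construction, transition probabilities through
## the spectral decomposition of the pi-symmetrized generator, and
## among-site rate heterogeneity (+G, +I).

#' Build the generator matrix of a substitution model
#'
#' Forms the instantaneous-rate matrix \code{Q[i,j] = M[i,j] * f[j]} (off
#' diagonal) with the diagonal set so rows sum to zero. With
#' \code{scale = TRUE} (default) the matrix is divided by the expected rate at
#' stationarity, \code{-sum(f * diag(Q))}, so branch lengths are measured in
#' expected substitutions per site — the convention assumed by the
#' phylogenetics tools these models are distributed for. The stationary
#' distribution equals \code{f} and detailed balance holds because \code{M} is
#' symmetric.
#'
#' Symbols with zero equilibrium frequency are dropped from the state space
#' with a warning (regularizing them would silently change the model).
#'
#' @param model a \linkS4class{RateModel} with strictly positive frequencies.
#' @param scale normalize the expected rate at stationarity to 1.
#' @return A \linkS4class{GeneratorMatrix}.
#' @export
#' @examples
#' m <- RateModel(matrix(1, 20, 20) - diag(20), name = "equal-rates")
#' buildGenerator(m)
buildGenerator <- function(model, scale = TRUE) {
  stopifnot(is(model, "RateModel"))
  M <- model@M; f <- model@f; ab <- model@alphabet
  if (any(f == 0)) {
    keep <- f > 0
    warning(sprintf("dropping %d zero-frequency state(s): %s",
                    sum(!keep), paste(ab[!keep], collapse = ", ")), call. = FALSE)
    M <- M[keep, keep, drop = FALSE]
    f <- f[keep] / sum(f[keep])
    ab <- ab[keep]
    if (length(ab) < 2L) .stopf("fewer than 2 states remain after dropping zero-frequency symbols")
  }
  if (max(M) <= 0) .stopf("degenerate model: all relative rates are zero")
  Q <- M * rep(f, each = nrow(M))       # Q[i, j] = M[i, j] * f[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  if (mu <= 0) .stopf("degenerate model: zero expected rate at stationarity")
  if (scale) Q <- Q / mu
  dimnames(Q) <- list(ab, ab)
  new("GeneratorMatrix", Q = Q, pi = f, alphabet = ab, scaled = scale)
}

## Spectral decomposition of the pi-symmetrized generator
## B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric under reversibility, so
## the spectrum is real and P(t) = diag(1/sqrt(pi)) V exp(L t) V' diag(sqrt(pi)).
## Returns a closure-friendly list reused across branches and rate categories.
.spectral <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2                    # symmetrize away rounding noise
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / s,                # diag(1/s) %*% V (row scaling)
       W = t(e$vectors * s))             # t(V) %*% diag(s)
}

.probFromSpectral <- function(sp, t) {
  P <- sp$U %*% (exp(sp$values * t) * sp$W)
  ## clip roundoff that strays marginally outside [0, 1]
  P[P < 0 & P > -1e-12] <- 0
  P[P > 1 & P < 1 + 1e-12] <- 1
  P
}

#' Transition probabilities over a branch
#'
#' Computes \code{P(t) = exp(Q t)} by symmetric eigendecomposition of the
#' pi-symmetrized generator, which is exact for the time-reversible models
#' handled here (real spectrum guaranteed). Entries are clipped to [0, 1]
#' only when within 1e-12 of the boundary.
#'
#' @param Q a \linkS4class{GeneratorMatrix}.
#' @param t nonnegative branch length (expected substitutions per site when
#'   \code{Q} is scaled).
#' @return A \linkS4class{TransitionMatrix}.
#' @export
#' @examples
#' g <- buildGenerator(RateModel(matrix(1, 20, 20) - diag(20)))
#' probMatrix(transitionMatrix(g, 0.1))[1:3, 1:3]
transitionMatrix <- function(Q, t) {
  stopifnot(is(Q, "GeneratorMatrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    .stopf("branch length t must be a single nonnegative number")
  sp <- .spectral(Q@Q, Q@pi)
  P <- .probFromSpectral(sp, t)
  dimnames(P) <- dimnames(Q@Q)
  new("TransitionMatrix", P = P, t = t, alphabet = Q@alphabet)
}

#' Discrete-gamma among-site rate variation
#'
#' Discretizes the Gamma(alpha, alpha) rate distribution (mean 1) into
#' \code{k} equal-probability categories whose rates are the distribution's
#' mean within each inter-quantile slice — the category-mean convention of
#' the standard model-selection tools. The probability-weighted mean of the
#' category rates is 1, preserving the branch-length scale.
#'
#' @param alpha gamma shape parameter (> 0); small values mean strong rate
#'   variation across sites, large values approach the homogeneous model.
#' @param k number of categories (default 4).
#' @return A \linkS4class{RateHeterogeneity} with \code{pInv = 0}.
#' @export
#' @examples
#' discreteGamma(0.5, 4)
discreteGamma <- function(alpha, k = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    .stopf("alpha must be a single positive number")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) .stopf("k must be a positive integer")
  if (k == 1L) {
    rates <- 1
  } else {
    breaks <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
    ## mean of Gamma(a, a) over a quantile slice, via the incomplete-gamma
    ## identity E[X; X in (lo, hi)] = F_{a+1}(hi) - F_{a+1}(lo)
    rates <- k * diff(pgamma(breaks, shape = alpha + 1, rate = alpha))
    rates <- rates / mean(rates)        # analytic mean is 1; remove roundoff
  }
  new("RateHeterogeneity", pInv = 0, alpha = alpha, k = k,
      rates = rates, probs = rep(1 / k, k))
}

#' Add an invariable-site category (+I)
#'
#' Adds a rate-zero category with probability \code{pInv} and rescales the
#' remaining category rates by \code{1 / (1 - pInv)} so the expected rate
#' over all sites stays 1.
#'
#' @param het a \linkS4class{RateHeterogeneity} without an invariant
#'   component (e.g. from \code{\link{discreteGamma}} or
#'   \code{\link{homogeneousRates}}).
#' @param pInv proportion of invariable sites in [0, 1]. The value 1 yields
#'   the fully frozen degenerate model (useful only for simulator edge-case
#'   checks).
#' @return A \linkS4class{RateHeterogeneity}.
#' @export
#' @examples
#' applyInvariant(homogeneousRates(), 0.25)  # rates (0, 4/3), probs (0.25, 0.75)
applyInvariant <- function(het, pInv) {
  stopifnot(is(het, "RateHeterogeneity"))
  if (!is.numeric(pInv) || length(pInv) != 1L || is.na(pInv) || pInv < 0 || pInv > 1)
    .stopf("pInv must be a single proportion in [0, 1]")
  if (het@pInv > 0) .stopf("het already carries an invariant category")
  if (pInv == 0) return(het)
  if (pInv == 1)
    return(new("RateHeterogeneity", pInv = 1, alpha = het@alpha, k = het@k,
               rates = 0, probs = 1))
  new("RateHeterogeneity", pInv = pInv, alpha = het@alpha, k = het@k,
      rates = c(0, het@rates / (1 - pInv)),
      probs = c(pInv, het@probs * (1 - pInv)))
}
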