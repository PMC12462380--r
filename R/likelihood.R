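## Alignment likelihood on a fixed tree (Felsenstein pruning) and BIC-based
## model selection. The tree and its branch lengths are fixed inputs; only
## the rate-heterogeneity parameters (gamma shape alpha, invariant proportion
## pInv, and optionally a global branch-scale factor) are optimized, each by
## bounded golden-section search (cyclic over axes for multi-parameter fits).

#' Compress an alignment to its unique site patterns
#'
#' Groups identical columns and records their multiplicities; likelihoods are
#' then computed once per pattern. Pattern order is the order of first
#' occurrence.
#'
#' @param alignment character matrix (taxa x sites).
#' @return List with \code{patterns} (taxa x nPattern character matrix),
#'   \code{counts} (multiplicities summing to the alignment length) and
#'   \code{index} (pattern index of each original column).
#' @export
sitePatternCompress <- function(alignment) {
  if (!is.matrix(alignment)) .stopf("alignment must be a character matrix")
  keys <- apply(alignment, 2L, paste0, collapse = "\r")
  fac <- factor(keys, levels = unique(keys))
  idx <- as.integer(fac)
  first <- match(levels(fac), keys)
  list(patterns = alignment[, first, drop = FALSE],
       counts = as.integer(tabulate(idx, nbins = nlevels(fac))),
       index = idx)
}

## Precompute everything reusable across likelihood evaluations for one
## (alignment, tree, model) triple: postorder edges, tip partial-likelihood
## indicator matrices (missing data = all-ones column), spectral
## decomposition of the generator.
.likContext <- function(alignment, tree, model) {
  stopifnot(is(model, "RateModel"), inherits(tree, "phylo"))
  if (!is.matrix(alignment)) .stopf("alignment must be a character matrix")
  if (is.null(rownames(alignment))) .stopf("alignment rows must be named by taxon")
  if (!setequal(rownames(alignment), tree$tip.label))
    .stopf("alignment taxa and tree leaves differ")
  gen <- buildGenerator(model, scale = TRUE)
  ab <- gen@alphabet
  nState <- length(ab)
  tr <- ape::reorder.phylo(tree, "postorder")
  cp <- sitePatternCompress(alignment[tr$tip.label, , drop = FALSE])
  nPat <- ncol(cp$patterns)
  tips <- lapply(seq_len(nrow(cp$patterns)), function(i) {
    st <- match(cp$patterns[i, ], ab)     # NA = gap/ambiguity = missing
    Lp <- matrix(0, nState, nPat)
    known <- !is.na(st)
    Lp[cbind(st[known], which(known))] <- 1
    Lp[, !known] <- 1
    Lp
  })
  list(gen = gen, sp = .spectral(gen@Q, gen@pi), tips = tips,
       counts = cp$counts, nPat = nPat, nState = nState,
       edge = tr$edge, elen = tr$edge.length, nTip = length(tr$tip.label),
       nNode = length(tr$tip.label) + tr$Nnode,
       constant = vapply(seq_len(nPat), function(j) {
         obs <- unique(cp$patterns[, j])
         length(setdiff(obs, c("-", ".", "?"))) <= 1L
       }, TRUE))
}

## per-pattern log-likelihood under one rate; returns log scale included
.patternLogLik <- function(ctx, rate, branchScale = 1) {
  if (rate == 0) {
    ## P = I: the pattern likelihood is f[x] for constant patterns, else 0
    lik <- rep(0, ctx$nPat)
    base <- Reduce(`*`, ctx$tips)                 # elementwise indicator product
    lik <- colSums(ctx$gen@pi * base)
    return(log(lik))
  }
  partial <- vector("list", ctx$nNode)
  logsc <- rep(0, ctx$nPat)
  for (e in seq_len(nrow(ctx$edge))) {
    ch <- ctx$edge[e, 2L]; p <- ctx$edge[e, 1L]
    Lch <- if (ch <= ctx$nTip) ctx$tips[[ch]] else partial[[ch]]
    P <- .probFromSpectral(ctx$sp, ctx$elen[e] * rate * branchScale)
    contrib <- P %*% Lch
    ## rescale against underflow; any positive per-column factor works and
    ## the column sum is cheap to take
    mx <- colSums(contrib)
    mx[mx <= 0] <- 1
    contrib <- contrib / rep(mx, each = ctx$nState)
    logsc <- logsc + log(mx)
    partial[[p]] <- if (is.null(partial[[p]])) contrib else partial[[p]] * contrib
  }
  root <- ctx$nTip + 1L
  log(colSums(ctx$gen@pi * partial[[root]])) + logsc
}

.lnLContext <- function(ctx, het, branchScale = 1) {
  k <- length(het@rates)
  ll <- matrix(-Inf, k, ctx$nPat)
  for (c in seq_len(k)) {
    if (het@probs[c] == 0) next
    ll[c, ] <- log(het@probs[c]) + .patternLogLik(ctx, het@rates[c], branchScale)
  }
  sum(ctx$counts * .logColSumExp(ll))
}

#' Alignment log-likelihood on a fixed tree
#'
#' Felsenstein pruning: partial likelihoods are accumulated post-order over
#' the tree, per unique site pattern, per rate category, with per-node
#' rescaling to guard against underflow. The site likelihood mixes the
#' categories by their probabilities and the root is weighted by the model's
#' equilibrium frequencies. Gaps and symbols outside the model alphabet are
#' treated as missing data (all-ones partial likelihood); an invariant
#' (rate-zero) category contributes \code{f[x]} only to constant-site
#' patterns.
#'
#' @param alignment character matrix (taxa x sites) with taxon rownames
#'   matching the tree's tip labels.
#' @param tree \code{ape::phylo} with branch lengths.
#' @param model a \linkS4class{RateModel}.
#' @param het a \linkS4class{RateHeterogeneity}; default homogeneous.
#' @return The log-likelihood (a scalar).
#' @export
logLikelihood <- function(alignment, tree, model, het = homogeneousRates()) {
  ctx <- .likContext(alignment, tree, model)
  .lnLContext(ctx, het)
}

## bounded 1-D maximization per axis: golden-section search with Brent's
## parabolic acceleration (stats::optimize); the bracket endpoints are also
## probed so boundary optima (e.g. alpha at the large-shape limit for
## homogeneous data) are not missed
.axisMax <- function(fn, lo, hi, tol = 2e-4) {
  res <- optimize(fn, lower = lo, upper = hi, maximum = TRUE,
                  tol = tol * (hi - lo))
  best <- list(x = res$maximum, f = res$objective)
  for (x in c(lo, hi)) {
    fx <- fn(x)
    if (fx > best$f) best <- list(x = x, f = fx)
  }
  best
}

#' Fit rate-heterogeneity parameters for one candidate
#'
#' Maximizes the pruning log-likelihood over the gamma shape \code{alpha}
#' (searched on a log scale within [0.02, 100]) and/or the invariable-site
#' proportion \code{pInv} within [0, 0.99], by bounded derivative-free search
#' per axis (golden section with parabolic acceleration, boundary probes
#' included) — cyclic over the axes when both (or a branch-scale factor) are
#' fitted, stopping when a full cycle improves the log-likelihood by less
#' than 1e-6. Non-convergence at the cycle cap is flagged and the best point
#' returned.
#'
#' @param alignment,tree as in \code{\link{logLikelihood}}.
#' @param candidate a \linkS4class{CandidateSpec}.
#' @param scaleBranches also fit a global branch-length multiplier (within
#'   [0.02, 50]); off by default since trees are fixed inputs.
#' @return List with \code{lnL}, \code{alpha} (NA unless fitted),
#'   \code{pInv} (NA unless fitted), \code{branchScale}, \code{het} (the
#'   fitted \linkS4class{RateHeterogeneity}) and \code{converged}.
#' @export
fitHeterogeneity <- function(alignment, tree, candidate, scaleBranches = FALSE) {
  stopifnot(is(candidate, "CandidateSpec"))
  ctx <- .likContext(alignment, tree, candidate@model)
  hetOf <- function(alpha, pInv) {
    base <- if (candidate@useGamma) discreteGamma(alpha, candidate@k)
            else homogeneousRates()
    if (candidate@useInv) applyInvariant(base, pInv) else base
  }
  alpha <- if (candidate@useGamma) 1 else NA_real_
  pInv <- if (candidate@useInv) 0.1 else NA_real_
  bs <- 1
  lnLOf <- function(a, p, s) .lnLContext(ctx, hetOf(a, p), s)

  axes <- c(if (candidate@useGamma) "alpha", if (candidate@useInv) "pInv",
            if (scaleBranches) "bs")
  if (!length(axes)) {
    return(list(lnL = lnLOf(alpha, pInv, bs), alpha = alpha, pInv = pInv,
                branchScale = bs, het = hetOf(alpha, pInv), converged = TRUE))
  }
  best <- lnLOf(alpha, pInv, bs)
  converged <- FALSE
  maxCycles <- if (length(axes) == 1L) 1L else 8L
  for (cycle in seq_len(maxCycles)) {
    prev <- best
    for (ax in axes) {
      ## after the first cycle the search brackets shrink around the current
      ## point, which makes the cyclic descent cheap on the alpha/pInv ridge
      res <- switch(ax,
        alpha = {
          lo <- if (cycle == 1L) log(0.02) else max(log(0.02), log(alpha) - 1.2)
          hi <- if (cycle == 1L) log(100) else min(log(100), log(alpha) + 1.2)
          .axisMax(function(x) lnLOf(exp(x), pInv, bs), lo, hi)
        },
        pInv = {
          lo <- if (cycle == 1L) 0 else max(0, pInv - 0.2)
          hi <- if (cycle == 1L) 0.99 else min(0.99, pInv + 0.2)
          .axisMax(function(x) lnLOf(alpha, x, bs), lo, hi)
        },
        bs = {
          lo <- if (cycle == 1L) log(0.02) else max(log(0.02), log(bs) - 1.2)
          hi <- if (cycle == 1L) log(50) else min(log(50), log(bs) + 1.2)
          .axisMax(function(x) lnLOf(alpha, pInv, exp(x)), lo, hi)
        })
      if (res$f >= best) {
        if (ax == "alpha") alpha <- exp(res$x)
        else if (ax == "pInv") pInv <- res$x
        else bs <- exp(res$x)
        best <- res$f
      }
    }
    if (length(axes) == 1L) { converged <- TRUE; break }
    if (best - prev < 1e-6) { converged <- TRUE; break }
  }
  list(lnL = best, alpha = alpha, pInv = pInv, branchScale = bs,
       het = hetOf(alpha, pInv), converged = converged)
}

#' Best-fit model selection by BIC
#'
#' Fits every candidate on the fixed tree, counts its free parameters (the
#' empirical matrix contributes 0; +G adds 1, +I adds 1, the optional branch
#' scale adds 1) and ranks by the Bayesian Information Criterion
#' \code{BIC = -2 lnL + kpar * log(nSites)} with the sample size taken as
#' the number of alignment sites — the convention of the standard
#' model-selection frameworks; note the choice of \code{n} can change
#' rankings. Ties are broken by fewer parameters, then by candidate name.
#'
#' @param alignment,tree as in \code{\link{logLikelihood}}.
#' @param candidates list of \linkS4class{CandidateSpec} (>= 2).
#' @param scaleBranches see \code{\link{fitHeterogeneity}}.
#' @return A data.frame sorted by ascending BIC with columns
#'   \code{candidate}, \code{lnL}, \code{alpha}, \code{p_inv}, \code{kpar},
#'   \code{BIC}, \code{rank}, \code{converged}; attribute \code{nSites}
#'   records the BIC sample size.
#' @export
selectModel <- function(alignment, tree, candidates, scaleBranches = FALSE) {
  if (length(candidates) < 2L) .stopf("at least 2 candidates are needed")
  nSites <- ncol(alignment)
  rows <- lapply(candidates, function(cand) {
    fit <- fitHeterogeneity(alignment, tree, cand, scaleBranches = scaleBranches)
    kpar <- cand@useGamma + cand@useInv + scaleBranches
    data.frame(candidate = candidateName(cand), lnL = fit$lnL,
               alpha = fit$alpha, p_inv = fit$pInv, kpar = kpar,
               BIC = -2 * fit$lnL + kpar * log(nSites),
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$BIC, out$kpar, out$candidate)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "nSites") <- nSites
  out
}

#' Write a model-selection report as TSV
#'
#' @param result data.frame from \code{\link{selectModel}}.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
writeSelectionReport <- function(result, file) {
  write.table(result, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
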