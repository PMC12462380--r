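## Shared fixtures and independent oracles used across the test files.
## Oracles are deliberately naive (enumeration, Taylor series, quadrature)
## and share no code with the implementation paths they check.

toyAlphabet <- c("a", "b", "c")

## 3-state toy: M = {{0,1,2},{1,0,3},{2,3,0}}, f = (0.5, 0.3, 0.2)
toyModel <- function() {
  RateModel(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, byrow = TRUE),
            c(0.5, 0.3, 0.2), alphabet = toyAlphabet, name = "toyA")
}

## equal-rates model: all off-diagonal exchangeabilities 1, uniform f
equalRatesModel <- function(n = 20L) {
  ab <- if (n == 20L) aminoAcids() else paste0("s", seq_len(n))
  RateModel(matrix(1, n, n) - diag(n), rep(1 / n, n), alphabet = ab,
            name = "equal-rates")
}

## Taylor-series matrix exponential: independent of the spectral route
taylorExpm <- function(A, nTerms = 60L) {
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (m in seq_len(nTerms)) {
    term <- term %*% A / m
    out <- out + term
  }
  out
}

## brute-force pruning oracle: sum over every assignment of internal-node
## states, per site, L = sum_a f[root_a] prod_edges P[state_parent, state_child]
enumLogLik <- function(alignment, tree, model, het = homogeneousRates()) {
  gen <- buildGenerator(model, scale = TRUE)
  ab <- alphabet(gen)
  nState <- length(ab)
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nInt <- tr$Nnode
  internals <- nTip + seq_len(nInt)
  Pcat <- lapply(het@rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(e)
      probMatrix(transitionMatrix(gen, tr$edge.length[e] * r))))
  tipStates <- lapply(tr$tip.label, function(tx) match(alignment[tx, ], ab))
  nSites <- ncol(alignment)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nState)), nInt)))
  total <- 0
  for (site in seq_len(nSites)) {
    siteL <- 0
    for (c in seq_along(het@rates)) {
      Ls <- 0
      for (g in seq_len(nrow(grid))) {
        stateOf <- function(node) {
          if (node <= nTip) tipStates[[node]][site]
          else grid[g, node - nTip]
        }
        pr <- gen@pi[grid[g, 1L]]  # node nTip+1 is the root
        for (e in seq_len(nrow(tr$edge))) {
          pr <- pr * Pcat[[c]][[e]][stateOf(tr$edge[e, 1L]), stateOf(tr$edge[e, 2L])]
        }
        Ls <- Ls + pr
      }
      siteL <- siteL + het@probs[c] * Ls
    }
    total <- total + log(siteL)
  }
  total
}

## patristic (path-length) distances of a tree, labeled
patristic <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

rfDistance <- function(t1, t2) phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))

## split-based monophyly on an unrooted tree: root at a leaf outside the set
isFamilyConnected <- function(tree, tips) {
  out <- setdiff(tree$tip.label, tips)[1L]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

randomToyModel <- function(seed, n = 4L) {
  randomModel(alphabet = paste0("s", seq_len(n)), seed = seed,
              name = paste0("rt", seed, "n", n))
}
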