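## Sequence evolution along a phylogeny.
##
## Simulation runs from the root toward the tips: each site is assigned a
## rate category once at the root (inherited along the whole tree, the
## standard +G semantics), and on every branch the child state is drawn from
## the row of P(rate * t) corresponding to the parent state. Only endpoint
## states are needed, so sampling endpoint distributions exactly beats
## event-by-event simulation.

#' Draw per-site evolutionary rates
#'
#' Assigns each site independently to a rate category according to the
#' category probabilities and returns the category rate per site.
#'
#' @param het a \linkS4class{RateHeterogeneity}.
#' @param nSites number of sites.
#' @param seed optional integer seed (NULL: current RNG stream).
#' @return Numeric vector of per-site rates.
#' @export
drawSiteRates <- function(het, nSites, seed = NULL) {
  stopifnot(is(het, "RateHeterogeneity"))
  draw <- function() {
    idx <- if (length(het@probs) == 1L) rep(1L, nSites)
           else sample.int(length(het@probs), nSites, replace = TRUE, prob = het@probs)
    het@rates[idx]
  }
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

.charToStates <- function(chars, alphabet) {
  st <- match(chars, alphabet)
  if (anyNA(st))
    .stopf("symbol(s) outside the model alphabet: %s",
           paste(unique(chars[is.na(st)]), collapse = ", "))
  st
}

#' Simulate amino-acid alignments along a phylogeny
#'
#' Evolves sequences from the root to the tips of \code{tree} under the CTMC
#' of \code{model} with optional among-site rate heterogeneity. The root
#' sequence is either fixed (e.g. the sequence of a representative protein)
#' or drawn i.i.d. from the model's equilibrium frequencies. Site rate
#' categories are drawn once per replicate and inherited along the tree; on a
#' branch of length \code{t}, a site with rate \code{r} transitions according
#' to \code{P(r t)}. Each replicate uses a seed derived deterministically
#' from \code{(seed, replicate)} by a fixed counter scheme, so runs are
#' reproducible and replicates independent.
#'
#' @param model a \linkS4class{RateModel}.
#' @param tree an \code{ape::phylo} with branch lengths in expected
#'   substitutions per site.
#' @param rootSequence \code{"equilibrium"} (draw the root from \code{f};
#'   requires \code{nSites}) or a character vector of residues / single
#'   string fixing the root.
#' @param nSites alignment length when the root is drawn from equilibrium.
#' @param het a \linkS4class{RateHeterogeneity}; default homogeneous.
#' @param replicates number of independent replicates (the stochasticity of
#'   the substitution process is usually summarized over many, e.g. 100).
#' @param seed master integer seed.
#' @return A list of \code{replicates} alignments; each is a character matrix
#'   with one row per tip (rownames = tip labels, in tree tip order) and one
#'   column per site.
#' @export
#' @examples
#' m <- RateModel(matrix(1, 20, 20) - diag(20), name = "equal-rates")
#' tr <- readNewick(text = "((A:0.1,B:0.2):0.05,C:0.3);")
#' aln <- simulateAlignment(m, tr, nSites = 50, seed = 1)[[1]]
#' dim(aln)
simulateAlignment <- function(model, tree, rootSequence = "equilibrium",
                              nSites = NULL, het = homogeneousRates(),
                              replicates = 1L, seed = 1L) {
  stopifnot(is(model, "RateModel"), inherits(tree, "phylo"),
            is(het, "RateHeterogeneity"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) .stopf("replicates must be >= 1")
  gen <- buildGenerator(model, scale = TRUE)
  ab <- gen@alphabet
  nState <- length(ab)
  sp <- .spectral(gen@Q, gen@pi)

  fixedRoot <- !(is.character(rootSequence) && length(rootSequence) == 1L &&
                 rootSequence == "equilibrium")
  if (fixedRoot) {
    chars <- if (length(rootSequence) == 1L)
      strsplit(rootSequence, "")[[1L]] else as.character(rootSequence)
    rootStates <- .charToStates(chars, ab)
    nSites <- length(rootStates)
  } else if (is.null(nSites)) {
    .stopf("nSites is required when the root sequence is drawn from equilibrium")
  }
  nSites <- as.integer(nSites)
  if (nSites < 1L) .stopf("nSites must be >= 1")

  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  if (is.null(elen)) .stopf("tree must have branch lengths")
  nTip <- length(tr$tip.label)
  root <- nTip + 1L
  nNode <- nTip + tr$Nnode
  kCat <- length(het@rates)

  lapply(seq_len(replicates), function(rep) {
    .withSeed(.deriveSeed(seed, rep), {
      siteCat <- if (kCat == 1L) rep(1L, nSites)
                 else sample.int(kCat, nSites, replace = TRUE, prob = het@probs)
      states <- matrix(0L, nNode, nSites)
      states[root, ] <- if (fixedRoot) rootStates
        else sample.int(nState, nSites, replace = TRUE, prob = gen@pi)
      ## parents before children: walk the postorder edge list backwards
      for (e in rev(seq_len(nrow(edge)))) {
        p <- edge[e, 1L]; ch <- edge[e, 2L]; t <- elen[e]
        childRow <- states[p, ]
        for (c in seq_len(kCat)) {
          tc <- t * het@rates[c]
          if (tc == 0) next  # invariant category or zero branch: copy parent
          sites <- which(siteCat == c)
          if (!length(sites)) next
          P <- .probFromSpectral(sp, tc)
          parStates <- states[p, sites]
          for (s in sort(unique(parStates))) {
            sel <- sites[parStates == s]
            childRow[sel] <- sample.int(nState, length(sel), replace = TRUE,
                                        prob = P[s, ])
          }
        }
        states[ch, ] <- childRow
      }
      aln <- matrix(ab[states[seq_len(nTip), , drop = FALSE]], nTip, nSites)
      rownames(aln) <- tr$tip.label
      aln
    })
  })
}

#' Pooled residue composition of an alignment
#'
#' @param alignment character matrix (taxa x sites) or named character vector
#'   of sequences.
#' @param alphabet symbol order for the returned vector; default the sorted
#'   symbols observed. Gap/missing symbols (\code{-}, \code{.}, \code{?})
#'   are excluded from the counts.
#' @return Named frequency vector summing to 1.
#' @export
composition <- function(alignment, alphabet = NULL) {
  chars <- if (is.matrix(alignment)) as.vector(alignment)
           else unlist(strsplit(as.character(alignment), ""))
  chars <- chars[!chars %in% c("-", ".", "?")]
  if (!length(chars)) .stopf("empty alignment")
  if (is.null(alphabet)) alphabet <- sort(unique(chars))
  counts <- vapply(alphabet, function(s) sum(chars == s), 0)
  counts / sum(counts)
}

#' Alignment FASTA I/O
#'
#' \code{readFastaAlignment} reads an equal-length FASTA alignment into the
#' package's character-matrix representation; \code{writeFastaAlignment}
#' writes one. Arbitrary residue alphabets are accepted.
#'
#' @param file path to a FASTA file.
#' @return \code{readFastaAlignment}: character matrix (taxa x sites).
#' @export
readFastaAlignment <- function(file) {
  seqs <- Biostrings::readBStringSet(file)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L) .stopf("sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(mat) <- names(seqs)
  mat
}

#' @rdname readFastaAlignment
#' @param alignment character matrix (taxa x sites) with rownames.
#' @export
writeFastaAlignment <- function(alignment, file) {
  seqs <- Biostrings::BStringSet(apply(alignment, 1L, paste0, collapse = ""))
  names(seqs) <- rownames(alignment)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
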