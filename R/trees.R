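## Newick I/O (through ape) and random phylogeny generation.

#' Read and write Newick trees
#'
#' Thin wrappers around \code{ape::read.tree}/\code{ape::write.tree} that add
#' the package's contracts: a parse failure is a proper error (not NULL),
#' missing branch lengths default to 0 with a warning, negative branch
#' lengths are rejected, and trees are written with 17 significant digits so
#' a write/read round trip preserves branch lengths to better than 1e-12.
#'
#' @param file path to a Newick file.
#' @param text alternatively, the Newick string itself.
#' @return \code{readNewick}: an \code{ape::phylo}; \code{writeNewick}:
#'   invisibly, the Newick string.
#' @export
#' @examples
#' tr <- readNewick(text = "((A:0.1,B:0.2):0.05,C:0.3);")
#' writeNewick(tr)
readNewick <- function(file = NULL, text = NULL) {
  phy <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL, warning = function(w) NULL)
  if (!inherits(phy, "phylo")) .stopf("failed to parse Newick input")
  if (anyDuplicated(phy$tip.label)) .stopf("leaf names must be unique")
  if (is.null(phy$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0", call. = FALSE)
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    warning("missing branch lengths; defaulting them to 0", call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0)) .stopf("negative branch length in tree")
  phy
}

#' @rdname readNewick
#' @param tree an \code{ape::phylo}.
#' @export
writeNewick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 17)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Random rooted binary phylogeny
#'
#' Grows a topology by sequential random attachment: starting from a
#' two-leaf tree, each further leaf is grafted onto a uniformly chosen
#' existing edge. Branch lengths are then drawn independently from the chosen
#' law. Leaves are named T1..Tn. Deterministic under \code{seed}.
#'
#' @param nTaxa number of leaves (>= 3).
#' @param branchLaw \code{"exponential"} (default) or \code{"uniform"}.
#' @param meanLength mean branch length for the exponential law (expected
#'   substitutions per site; default 0.1).
#' @param minLength,maxLength bounds for the uniform law.
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return A rooted binary \code{ape::phylo} with positive branch lengths.
#' @export
#' @examples
#' randomTree(6, seed = 1)
randomTree <- function(nTaxa, branchLaw = c("exponential", "uniform"),
                       meanLength = 0.1, minLength = 0.05, maxLength = 0.5,
                       seed = NULL) {
  branchLaw <- match.arg(branchLaw)
  nTaxa <- as.integer(nTaxa)
  if (is.na(nTaxa) || nTaxa < 3L) .stopf("nTaxa must be at least 3")
  build <- function() {
    ## leaves are 1..nTaxa; internal nodes negative (root = -1)
    par <- c(-1L, -1L)
    chi <- c(1L, 2L)
    nextInt <- -2L
    for (k in 3:nTaxa) {
      e <- sample.int(length(par), 1L)
      par <- c(par, nextInt, nextInt)
      chi <- c(chi, chi[e], k)
      chi[e] <- nextInt
      nextInt <- nextInt - 1L
    }
    len <- switch(branchLaw,
                  exponential = rexp(length(par), rate = 1 / meanLength),
                  uniform = runif(length(par), minLength, maxLength))
    kids <- split(seq_along(par), par)
    rec <- function(node) {
      e <- which(chi == node)
      suffix <- if (length(e)) paste0(":", .fmt(len[e])) else ""
      if (node > 0L) return(paste0("T", node, suffix))
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(chi[ch], rec, ""), collapse = ","), ")", suffix)
    }
    ape::read.tree(text = paste0(rec(-1L), ";"))
  }
  if (is.null(seed)) build() else .withSeed(seed, build())
}
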