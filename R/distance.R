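## Inter-model distances and neighbor-joining clustering.
##
## Models are compared after max-normalizing the relative-rate matrix
## (each rate divided by the largest rate in its matrix), because rate scales
## vary across published models. The distance is the mean absolute difference
## over corresponding entries: the n(n-1)/2 unordered off-diagonal rate pairs
## in "rates" mode, the n frequencies in "freqs" mode, and the arithmetic
## mean of the two (equal contribution) in "combined" mode.

#' Max-normalize a model's relative rates
#'
#' Divides every relative rate by the largest rate in the matrix, so the
#' maximum becomes exactly 1. Idempotent and invariant to overall rate scale.
#'
#' @param model a \linkS4class{RateModel}.
#' @return The model with normalized \code{M} (frequencies untouched).
#' @export
normalizeRates <- function(model) {
  stopifnot(is(model, "RateModel"))
  mx <- max(model@M)
  if (mx <= 0) .stopf("degenerate model: all relative rates are zero")
  RateModel(model@M / mx, model@f, alphabet = model@alphabet,
            name = model@name, freqFree = model@freqFree)
}

.checkSameAlphabet <- function(a, b) {
  if (!identical(a@alphabet, b@alphabet))
    .stopf("models '%s' and '%s' have different alphabets", a@name, b@name)
}

#' Distances between two substitution models
#'
#' \code{rateDistance} is the mean absolute difference between corresponding
#' max-normalized relative rates, taken over the unordered off-diagonal pairs
#' (the diagonal is structurally zero and would only dilute the value).
#' \code{freqDistance} is the mean absolute difference between equilibrium
#' frequencies. \code{combinedDistance} averages the two with equal
#' contribution; both component distances are already per-entry means, which
#' puts the rate and frequency blocks on comparable scales.
#'
#' @param a,b \linkS4class{RateModel}s over the same alphabet.
#' @return Nonnegative scalar distance.
#' @export
#' @examples
#' toyA <- RateModel(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3),
#'                   c(0.5, 0.3, 0.2), alphabet = c("a", "b", "c"), name = "A")
#' toyB <- RateModel(matrix(1, 3, 3) - diag(3), alphabet = c("a", "b", "c"), name = "B")
#' rateDistance(toyA, toyB)      # 1/3
#' freqDistance(toyA, toyB)      # 0.1111...
#' combinedDistance(toyA, toyB)  # 0.2222...
rateDistance <- function(a, b) {
  .checkSameAlphabet(a, b)
  am <- normalizeRates(a)@M
  bm <- normalizeRates(b)@M
  ut <- upper.tri(am)
  mean(abs(am[ut] - bm[ut]))
}

#' @rdname rateDistance
#' @export
freqDistance <- function(a, b) {
  .checkSameAlphabet(a, b)
  mean(abs(a@f - b@f))
}

#' @rdname rateDistance
#' @export
combinedDistance <- function(a, b) {
  (rateDistance(a, b) + freqDistance(a, b)) / 2
}

#' Pairwise distance matrix over a set of models
#'
#' @param models list of \linkS4class{RateModel}s sharing one alphabet, with
#'   unique names.
#' @param mode distance mode: \code{"combined"} (default), \code{"rates"}, or
#'   \code{"freqs"}.
#' @return A \linkS4class{ModelDistanceMatrix}.
#' @export
modelDistanceMatrix <- function(models, mode = c("combined", "rates", "freqs")) {
  mode <- match.arg(mode)
  if (length(models) < 2L) .stopf("at least 2 models are needed")
  labels <- vapply(models, modelName, "")
  if (anyDuplicated(labels)) .stopf("model names must be unique")
  fn <- switch(mode, rates = rateDistance, freqs = freqDistance,
               combined = combinedDistance)
  m <- length(models)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    D[i, j] <- D[j, i] <- fn(models[[i]], models[[j]])
  }
  new("ModelDistanceMatrix", labels = labels, D = D, mode = mode)
}

#' Write a distance matrix as PHYLIP or TSV
#'
#' @param D a \linkS4class{ModelDistanceMatrix}.
#' @param file output path.
#' @param format \code{"phylip"} (square, count on the first line) or
#'   \code{"tsv"} (header row and labeled rows).
#' @return Invisibly, the lines written.
#' @export
writeDistanceMatrix <- function(D, file = NULL, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(D, "ModelDistanceMatrix"))
  rows <- vapply(seq_along(D@labels), function(i)
    paste(c(D@labels[i], .fmt(D@D[i, ])), collapse = if (format == "tsv") "\t" else " "), "")
  lines <- if (format == "phylip") c(sprintf("%5d", length(D@labels)), rows)
           else c(paste(c("model", D@labels), collapse = "\t"), rows)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

## ---------------------------------------------------------------------------
## Neighbor joining
## ---------------------------------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration: repeatedly join the pair minimizing the
#' rate-corrected criterion \code{(n - 2) d(i,j) - r_i - r_j}, with branch
#' lengths from the three-point formulas, until three nodes remain, then
#' resolve the central trifurcation. Two determinism/robustness rules are
#' fixed: ties on the criterion are broken by the lexicographically smallest
#' label pair (each cluster is labeled by its smallest leaf name), and a
#' negative branch length is clamped to zero with the deficit transferred to
#' its sister branch, which preserves the path length through the new node
#' and never alters the topology. Consistent on additive distances: patristic
#' distances of a binary tree recover that tree exactly.
#'
#' @param D a \linkS4class{ModelDistanceMatrix}, or a symmetric numeric
#'   matrix with dimnames.
#' @return An unrooted \code{ape::phylo} tree whose tips are the labels.
#' @export
njTree <- function(D) {
  if (is(D, "ModelDistanceMatrix")) {
    labels <- D@labels
    d <- D@D
  } else {
    d <- as.matrix(D)
    labels <- rownames(d)
    if (is.null(labels)) .stopf("distance matrix must carry labels as dimnames")
  }
  n <- length(labels)
  if (n < 3L) .stopf("neighbor joining needs at least 3 labels")
  if (any(grepl("[(),:;\\[\\]']", labels)))
    .stopf("labels must not contain Newick metacharacters")

  ## active nodes: newick fragment + tie-break label (smallest leaf in clade)
  nwk <- labels
  tie <- labels
  repeat {
    m <- length(nwk)
    if (m == 3L) break
    r <- rowSums(d)
    crit <- (m - 2) * d - outer(r, r, "+")
    diag(crit) <- Inf
    best <- min(crit)
    cand <- which(crit - best <= 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(ij) {
        p <- sort(c(tie[ij[1]], tie[ij[2]]))
        paste(p, collapse = "\r")
      })
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    newNwk <- sprintf("(%s:%s,%s:%s)", nwk[i], .fmt(bi), nwk[j], .fmt(bj))
    newTie <- min(tie[i], tie[j])
    others <- setdiff(seq_len(m), c(i, j))
    dNew <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- rbind(cbind(d[others, others, drop = FALSE], dNew),
               c(dNew, 0))
    nwk <- c(nwk[others], newNwk)
    tie <- c(tie[others], newTie)
  }
  ## resolve the final three nodes around the central vertex
  x1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  x2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  x3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  x1 <- max(x1, 0); x2 <- max(x2, 0); x3 <- max(x3, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], .fmt(x1), nwk[2], .fmt(x2),
                 nwk[3], .fmt(x3))
  ape::read.tree(text = txt)
}
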