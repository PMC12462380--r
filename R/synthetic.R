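## Synthetic data: random reversible models, perturbation families that mimic
## taxon-group structure, and complete on-disk fixture sets, so every stage
## of the pipeline can be exercised without downloading any published model.

#' Random reversible substitution model
#'
#' Draws one exchangeability per unordered symbol pair i.i.d. from a
#' log-normal law (median 1; the heavy right tail mimics the rate spread of
#' empirical matrices) and equilibrium frequencies from a symmetric Dirichlet
#' with per-symbol concentration \code{frequencyConcentration}. The default
#' concentration 2 yields frequency vectors spread roughly like published
#' empirical models (about 0.005–0.15 across 20 symbols). Deterministic
#' under \code{seed}.
#'
#' @param alphabet residue symbols (default 20 amino acids).
#' @param seed integer seed.
#' @param frequencyConcentration per-symbol Dirichlet concentration (> 0);
#'   large values approach uniform frequencies.
#' @param rateMeanlog,rateSdlog parameters of the log-normal exchangeability
#'   law.
#' @param name model name.
#' @return A \linkS4class{RateModel}.
#' @export
#' @examples
#' randomModel(seed = 1)
randomModel <- function(alphabet = aminoAcids(), seed = 1L,
                        frequencyConcentration = 2, rateMeanlog = 0,
                        rateSdlog = 1, name = paste0("rnd", seed)) {
  n <- length(alphabet)
  stopifnot(n >= 2L, frequencyConcentration > 0)
  .withSeed(seed, {
    M <- matrix(0, n, n)
    M[lower.tri(M)] <- rlnorm(n * (n - 1) / 2, rateMeanlog, rateSdlog)
    M <- M + t(M)
    g <- rgamma(n, shape = frequencyConcentration)
    g <- pmax(g, 1e-300)
    RateModel(M, g / sum(g), alphabet = alphabet, name = name)
  })
}

#' Perturb a model to create a family member
#'
#' Multiplies each max-normalized exchangeability by \code{exp(epsilon * z)}
#' with independent standard-normal \code{z} (multiplicative log-normal
#' noise: preserves positivity without clipping artifacts) and resamples the
#' frequencies from a Dirichlet centered at the base frequencies with total
#' concentration \code{1 / epsilon}. With \code{epsilon = 0} the base model
#' is returned unchanged (up to rate normalization), so its combined distance
#' to the result is 0. Deterministic under \code{seed}.
#'
#' @param base a \linkS4class{RateModel}.
#' @param epsilon perturbation scale, \code{0 <= epsilon < 1}.
#' @param seed integer seed.
#' @param name name for the perturbed model.
#' @return A \linkS4class{RateModel}.
#' @export
perturbModel <- function(base, epsilon, seed = 1L,
                         name = paste0(base@name, "_p", seed)) {
  stopifnot(is(base, "RateModel"))
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon >= 1)
    .stopf("epsilon must lie in [0, 1)")
  norm <- normalizeRates(base)
  if (epsilon == 0)
    return(RateModel(norm@M, norm@f, alphabet = norm@alphabet, name = name))
  n <- length(base@alphabet)
  .withSeed(seed, {
    M <- norm@M
    z <- matrix(0, n, n)
    z[lower.tri(z)] <- rnorm(n * (n - 1) / 2)
    z <- z + t(z)
    M <- M * exp(epsilon * z)
    g <- rgamma(n, shape = norm@f / epsilon)
    g <- pmax(g, 1e-300)
    RateModel(M, g / sum(g), alphabet = norm@alphabet, name = name)
  })
}

#' Generate families of related models
#'
#' Emulates groups of empirical models derived from related proteins: each
#' family is one random base model plus small perturbations of it. Member 1
#' of each family is the base itself.
#'
#' @param nFamilies number of families.
#' @param membersPerFamily models per family (base + perturbations).
#' @param epsilon perturbation scale passed to \code{\link{perturbModel}}.
#' @param seed master seed; family and member seeds are derived from it.
#' @param alphabet,frequencyConcentration passed to \code{\link{randomModel}}.
#' @return List of \code{nFamilies} lists of \linkS4class{RateModel}s, named
#'   \code{F<i>M<j>}.
#' @export
modelFamilies <- function(nFamilies = 4L, membersPerFamily = 4L,
                          epsilon = 0.05, seed = 1L,
                          alphabet = aminoAcids(), frequencyConcentration = 2) {
  lapply(seq_len(nFamilies), function(f) {
    base <- randomModel(alphabet, seed = .deriveSeed(seed, 900000L + f),
                        frequencyConcentration = frequencyConcentration,
                        name = sprintf("F%dM1", f))
    members <- list(base)
    for (m in seq_len(membersPerFamily - 1L)) {
      members[[m + 1L]] <- perturbModel(base, epsilon,
                                        seed = .deriveSeed(seed, 1000L * f + m),
                                        name = sprintf("F%dM%d", f, m + 1L))
    }
    members
  })
}

#' Write a complete synthetic fixture set
#'
#' Produces on disk everything the pipeline consumes: a model catalog
#' (families of perturbed models in PAML format plus metadata, one taxonomic
#' group label per family), a random phylogeny in Newick, simulated
#' alignments in FASTA (\code{rep_0001.fasta} naming), and a
#' \code{manifest.tsv} recording every artifact's seed and parameters.
#' Regenerating with the same arguments reproduces every file byte for byte.
#'
#' @param dir output directory.
#' @param nFamilies,membersPerFamily,epsilon,seed,alphabet passed to
#'   \code{\link{modelFamilies}}.
#' @param nTaxa,meanLength random-tree parameters.
#' @param nSites,alpha,replicates simulation parameters (alignments are
#'   simulated under the first family's base model with discrete-gamma
#'   heterogeneity of shape \code{alpha}).
#' @return Invisibly, the manifest data.frame.
#' @export
makeFixtureSet <- function(dir, nFamilies = 4L, membersPerFamily = 4L,
                           epsilon = 0.05, seed = 1L, alphabet = aminoAcids(),
                           nTaxa = 16L, meanLength = 0.1, nSites = 300L,
                           alpha = 0.5, replicates = 2L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fams <- modelFamilies(nFamilies, membersPerFamily, epsilon, seed, alphabet)
  groups <- rep(c("nuclear_general", "mitochondrial", "chloroplast", "viral",
                  "nuclear_taxon_specific", "other"),
                length.out = nFamilies)
  records <- unlist(lapply(seq_len(nFamilies), function(f) {
    lapply(fams[[f]], function(m)
      ModelRecord(m, taxonomicGroup = groups[f], year = 1990L + f,
                  authors = "synthetic", reference = "generated in-package",
                  comments = sprintf("family %d, epsilon %g", f, epsilon)))
  }), recursive = FALSE)
  writeModelCatalog(records, dir)

  treeSeed <- .deriveSeed(seed, 500000L)
  tree <- randomTree(nTaxa, meanLength = meanLength, seed = treeSeed)
  writeNewick(tree, file.path(dir, "tree.nwk"))

  simSeed <- .deriveSeed(seed, 600000L)
  alns <- simulateAlignment(fams[[1L]][[1L]], tree, nSites = nSites,
                            het = discreteGamma(alpha, 4L),
                            replicates = replicates, seed = simSeed)
  for (r in seq_along(alns)) {
    writeFastaAlignment(alns[[r]], file.path(dir, sprintf("rep_%04d.fasta", r)))
  }

  manifest <- data.frame(
    artifact = c("catalog", "tree.nwk", "alignments"),
    seed = c(seed, treeSeed, simSeed),
    parameters = c(
      sprintf("nFamilies=%d;membersPerFamily=%d;epsilon=%.17g", nFamilies,
              membersPerFamily, epsilon),
      sprintf("nTaxa=%d;meanLength=%.17g", nTaxa, meanLength),
      sprintf("model=F1M1;nSites=%d;alpha=%.17g;k=4;replicates=%d", nSites,
              alpha, replicates)),
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
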