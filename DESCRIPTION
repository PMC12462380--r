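Package: SubstModelKit
Title: Empirical Amino Acid Substitution Models: I/O, Distances, Simulation and Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with empirical amino-acid substitution models of
    protein evolution. Reads and writes relative-rate and score matrices in the
    PAML text format together with catalog metadata; builds time-reversible
    generator matrices and transition probabilities with discrete-gamma and
    invariant-site rate heterogeneity; computes normalized inter-model distances
    (relative rates, equilibrium frequencies, or both with equal contribution)
    and clusters models by neighbor joining; simulates protein evolution from
    the root to the tips of a phylogeny with replicates; computes alignment
    likelihoods on a fixed tree by Felsenstein pruning and selects the
    best-fitting model by the Bayesian Information Criterion; and generates
    synthetic model families, trees and alignments so the whole pipeline can be
    exercised offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
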