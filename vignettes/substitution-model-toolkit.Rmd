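---
title: "Working with empirical amino-acid substitution models"
author: "SubstModelKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with empirical amino-acid substitution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SubstModelKit)
```

## The model class and its mathematics

Empirical substitution models of protein evolution are the workhorse of
likelihood-based protein phylogenetics. Each model consists of a symmetric
matrix $M$ of relative rates of change between amino-acid pairs ("exchangeabilities"),
estimated once from a large protein database, and a vector $f$ of equilibrium
amino-acid frequencies. Together they define the generator of a time-reversible
continuous-time Markov chain,

$$Q_{ij} = M_{ij}\, f_j \quad (i \ne j), \qquad
  Q_{ii} = -\sum_{j \ne i} Q_{ij},$$

and substitution probabilities over a branch of length $t$,
$P(t) = e^{Qt}$. In the literature the product $M_{ij} f_j$ is itself sometimes
called the exchangeability matrix; this package follows the mainstream naming
($M$ = exchangeabilities, $Q$ = generator) while implementing exactly that
formula. Detailed balance $\pi_i Q_{ij} = \pi_j Q_{ji}$ holds by construction
because $M$ is symmetric, and $\pi = f$.

Two conventions are fixed deliberately:

* **Branch-length scaling.** `buildGenerator()` divides $Q$ by the expected
  rate at stationarity ($-\sum_i f_i Q_{ii}$) by default, so branch lengths
  mean expected substitutions per site. Every phylogenetics framework these
  models are distributed for assumes this scale, and all distributed trees use
  it; the unscaled generator is available with `scale = FALSE`.
* **Matrix exponential.** $P(t)$ is computed by symmetric eigendecomposition of
  $\mathrm{diag}(\sqrt{\pi})\, Q\, \mathrm{diag}(1/\sqrt{\pi})$, which has a
  guaranteed real spectrum under reversibility. Entries are clipped to $[0,1]$
  only when within $10^{-12}$ of the boundary; anything further out would be a
  bug, not roundoff, and is left visible. Non-reversible generators are not
  constructed in the first place (the model classes enforce symmetry of $M$).

The alphabet is generic ($n \ge 2$): 3–5 state toy models exercise every
algorithm in the test suite, while 20-state amino-acid models in PAML order
(`aminoAcids()`) are the default and the scientific use case.

## Model files and the catalog

`parsePaml()`/`writePaml()` speak the de facto interchange dialect for these
models: $n-1$ lower-triangular rows *without* the diagonal, then a line of $n$
frequencies. Files carrying $n$ rows (with diagonal) are rejected with an
explanatory message rather than guessed at — silent misreads of a rate matrix
are far costlier than a re-export. Frequencies off by at most $10^{-3}$ from 1
(published rounding) are renormalized with a warning; larger deviations are
treated as corrupt input. A model file with no frequency block is given the
uniform default and *flagged* (`isFrequencyFree()`), because analyses that mix
frequency information across models — the combined distance below — may
legitimately want to exclude such models rather than compare a published $f$
against a default.

`ModelRecord` attaches the catalog metadata (kind, taxonomic group, year,
authors, reference, comments); `filterRecords()` reproduces a model database's
query surface (filter by any combination of fields, sort by one). Persistence
is deliberately plain text: a `metadata.tsv` plus one model file per record.
An indexed store would be an optimization, not a contract.

## Distances between models and the clustering analysis

Published models use arbitrary overall rate scales, so rate matrices are first
max-normalized: every entry divided by the largest entry in its matrix
(`normalizeRates()`, idempotent and scale-invariant). Distances are mean
absolute differences between corresponding entries:

* `rateDistance()` — over the $n(n-1)/2$ unordered off-diagonal pairs of the
  normalized $M$. The diagonal is structurally zero and excluded; including it
  would only dilute every distance by the same factor.
* `freqDistance()` — over the $n$ equilibrium frequencies.
* `combinedDistance()` — the arithmetic mean of the two. "Equal contribution"
  is read literally: both components are already per-entry means, which puts a
  190-entry rate vector and a 20-entry frequency vector on comparable scales
  before averaging.

The distances operate on $M$, not on the product $M f$: relative substitution
rates and frequencies are kept as separate axes of comparison, and the combined
mode is where frequency information enters. All three are pseudometrics on
normalized models (symmetry, zero self-distance, triangle inequality — property
tested).

`njTree()` clusters a model distance matrix by standard Saitou–Nei neighbor
joining. Two rules are fixed for determinism and robustness: ties on the
joining criterion break toward the lexicographically smallest label pair (each
cluster labeled by its smallest leaf), and a negative branch length is clamped
to zero with the deficit moved to its sister branch, preserving the path length
through the new node without ever altering the topology. On additive distances
NJ is consistent: patristic distances of any binary tree with positive branch
lengths recover that tree exactly, which the tests verify against an
independent NJ implementation.

## Simulation along a phylogeny

`simulateAlignment()` evolves sequences from the root toward the tips. Site
rate categories (+G discretized gamma, +I invariable sites, via
`discreteGamma()` and `applyInvariant()`) are drawn once per replicate at the
root and inherited along the entire tree — the standard +G semantics. Redrawing
rates per branch would average the heterogeneity away and destroy precisely the
signal the +G parameter encodes. On each branch the child state is sampled from
the row of $P(r\,t)$ for the site's rate $r$; only endpoint states matter for
alignments, so exact endpoint sampling is preferred over event-by-event
simulation. The root is either fixed (the typical design: the sequence of a
representative protein structure) or drawn i.i.d. from $f$.

`discreteGamma()` uses $k$ equal-probability categories with *category-mean*
rates (computed from the incomplete-gamma identity, so the mean rate is exactly
1), $k = 4$ by default — the dominant convention of model-selection tools.
Median-based categories are not offered.

Replicate $r$ runs under a seed derived from the master seed by a fixed
counter scheme (`seed + 104729 * r mod (2^31 - 1)`), so a 100-replicate study is
reproducible run-to-run and replicates are independent; each replicate redraws
site rates and all states. Indels are not simulated (the downstream analyses
these simulations feed replace indels anyway).

## Likelihood and model selection

`logLikelihood()` implements Felsenstein pruning over unique site patterns
(`sitePatternCompress()`), with per-edge rescaling of partial likelihoods so
200-taxon alignments with short branches stay finite. Gaps and out-of-alphabet
symbols are missing data (all-ones partials). The rate-zero invariant category
needs no special casing: $P(0) = I$ makes it contribute $f_x$ exactly for
constant patterns and 0 otherwise.

`selectModel()` ranks candidates (`candidateSpec()`: a model plus +G/+I flags)
by BIC $= -2\ln L + k\,\ln n$. Conventions, stated because they change
rankings:

* $n$ is the number of alignment **sites**, the convention of the standard
  model-selection frameworks.
* The empirical matrix contributes **0** free parameters (its entries were
  estimated from databases, not from the study data); +G and +I contribute one
  each. Frequencies come from the model file and are never re-estimated (+F
  variants are out of scope).
* Tree topology and branch lengths are fixed inputs and not counted. A global
  branch-scale multiplier can be fitted (`scaleBranches = TRUE`), in which case
  it is counted; it is off by default.
* BIC ties break by fewer parameters, then candidate name — deterministic
  output for identical fits.

Parameter fitting is bounded derivative-free search per axis ($\alpha$ on a log
scale in $[0.02, 100]$, $p_{\mathrm{inv}} \in [0, 0.99]$): golden-section with
parabolic (Brent) acceleration plus explicit boundary probes, cyclic over axes
for multi-parameter fits, stopping when a cycle gains less than $10^{-6}$
log-units. After the first cycle the brackets shrink around the current point,
which keeps the cyclic descent cheap on the classic $\alpha$/$p_{\mathrm{inv}}$
ridge. On that ridge an +I+G fit can still be improving by more than $10^{-6}$
per cycle at the cycle cap; it is then flagged `converged = FALSE` and the best
point returned — with near-identical likelihoods to the +G fit, as the ridge
implies.

## The synthetic-data generator

Nothing in the package depends on downloading published matrices; the
generator produces statistically analogous inputs:

* `randomModel()` draws exchangeabilities i.i.d. log-normal (median 1,
  $\sigma = 1$ — the heavy right tail mimics the rate spread of empirical
  matrices) and frequencies from a symmetric Dirichlet with per-symbol
  concentration 2, giving frequency vectors spread roughly like published
  models (about 0.005–0.15 over 20 residues).
* `perturbModel()` builds "families" (the analog of taxon-group structure
  among published models): multiplicative log-normal noise
  $e^{\varepsilon z}$ on normalized rates — additive noise would need clipping
  to stay positive — and Dirichlet resampling of frequencies centered at the
  base with total concentration $1/\varepsilon$.
* `randomTree()` grows a topology by sequential random attachment to a
  uniformly chosen edge and draws branch lengths exponential with mean 0.1
  substitutions/site — a typical scale for the protein-family alignments these
  pipelines target.
* `makeFixtureSet()` writes a complete catalog + tree + alignments + manifest
  to disk; with equal arguments the regeneration is byte-identical (all
  writers format at 17 significant digits).

What the generator does *not* emulate: the gap structure of real alignments,
site-specific selective constraints (all sites share one exchangeability
matrix), and the particular numerical content of any published model. Passing
tests therefore demonstrate the correctness of the machinery under the stated
stochastic models — not that any specific published matrix is reproduced.

## Problem sizes and numerical checks

The shipped end-to-end checks use deliberately chosen desk-scale sizes: the
clustering analog runs 4 families × 4 members at $\varepsilon = 0.05$ over 20
seeded runs; the selection analog simulates $L = 1000$ sites on 16-taxon trees
(exponential branches, mean 0.1) at $\alpha = 0.5$ over 20 replicates with six
candidates; calibration uses 20,000–100,000 sites on one or two branches.
These sizes give the statistics enough resolution to expose a wrong formula
(e.g. a mis-scaled generator shifts every transition-frequency band) while
keeping a full run in minutes on one core.

Numerical tolerances follow the structure of each computation: algebraic
identities (row sums, detailed balance, BIC arithmetic) are checked near
machine precision; spectral-vs-Taylor and pruning-vs-enumeration agreement at
$10^{-9}$–$10^{-10}$; stochastic calibrations at exact 99.73% binomial bands
with the multiplicity allowance that a 400-band family requires (the expected
number of 3$\sigma$ exceedances in 400 correct bands is already above one).

## Known limitations

* Only time-reversible models; no codon/nucleotide, structurally constrained,
  site-specific, or non-reversible processes.
* No tree search or branch-length optimization — trees are fixed inputs by
  design; model selection conditions on them.
* No +F (data-driven frequency) variants, no AIC/AICc, no bootstrap support on
  model dendrograms, no indel simulation, and no distances between score
  matrices (score models are I/O-supported and cataloged only).
* Frequency-free published files receive a flagged uniform $f$; whether such
  models should enter a combined-distance clustering is the analyst's call,
  which is why the flag exists.
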