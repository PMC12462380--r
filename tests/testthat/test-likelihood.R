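simAln <- function(model, tree, nSites, seed, het = homogeneousRates()) {
  simulateAlignment(model, tree, nSites = nSites, het = het, seed = seed)[[1]]
}

test_that("site pattern compression groups columns and preserves likelihoods", {
  aln <- matrix(rep(c("A", "R"), 5), 2, 5, dimnames = list(c("t1", "t2"), NULL))
  cp <- sitePatternCompress(aln)
  expect_equal(ncol(cp$patterns), 1L)
  expect_equal(cp$counts, 5L)

  set.seed(5)
  m <- randomToyModel(seed = 61, n = 4L)
  tr <- randomTree(4, seed = 61)
  aln <- simAln(m, tr, 60, seed = 3)
  cp <- sitePatternCompress(aln)
  expect_equal(sum(cp$counts), 60L)
  ## dictionary-grouping oracle
  keys <- apply(aln, 2, paste, collapse = "|")
  expect_equal(sort(cp$counts), sort(unname(table(keys))), ignore_attr = TRUE)
  ## first-occurrence order
  expect_equal(cp$patterns[, 1], aln[, 1])
  ## likelihood on duplicated columns scales linearly in the multiplicity
  dup <- aln[, rep(1:10, 3)]
  expect_equal(logLikelihood(dup, tr, m),
               3 * logLikelihood(aln[, 1:10], tr, m), tolerance = 1e-10)
})

test_that("no-evolution alignments have lnL = sum log f", {
  m <- toyModel()
  tr <- readNewick(text = "(t1:0,t2:0);")
  sites <- c("a", "b", "b", "c", "a")
  aln <- matrix(rep(sites, each = 2), 2, length(sites),
                dimnames = list(c("t1", "t2"), NULL))
  f <- equilibriumFreqs(m)[match(sites, alphabet(m))]
  expect_equal(logLikelihood(aln, tr, m), sum(log(f)), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration over internal states", {
  set.seed(6)
  for (i in 1:10) {
    nTaxa <- sample(3:5, 1)
    nStates <- sample(3:4, 1)
    m <- randomToyModel(seed = 70 + i, n = nStates)
    tr <- randomTree(nTaxa, meanLength = 0.3, seed = 70 + i)
    het <- if (i %% 2 == 0) discreteGamma(0.7, 2) else homogeneousRates()
    aln <- simAln(m, tr, 8, seed = i, het = het)
    expect_equal(logLikelihood(aln, tr, m, het),
                 enumLogLik(aln, tr, m, het), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to rerooting (pulley principle)", {
  m <- randomModel(seed = 81)
  tr <- randomTree(8, seed = 81)
  aln <- simAln(m, tr, 120, seed = 4)
  base <- logLikelihood(aln, tr, m, discreteGamma(0.5, 4))
  un <- ape::unroot(tr)
  expect_equal(logLikelihood(aln, un, m, discreteGamma(0.5, 4)), base,
               tolerance = 1e-9)
  for (tip in c("T2", "T5")) {
    rr <- ape::root(un, outgroup = tip, resolve.root = TRUE)
    expect_equal(logLikelihood(aln, rr, m, discreteGamma(0.5, 4)), base,
                 tolerance = 1e-9)
  }
})

test_that("pruning agrees with an established implementation on WAG", {
  ## phangorn ships the WAG model; build the same model here and compare
  wag <- get(".WAG", envir = asNamespace("phangorn"))
  M <- matrix(0, 20, 20)
  M[lower.tri(M)] <- wag$Q
  m <- RateModel(M + t(M), wag$bf, alphabet = Biostrings::AA_STANDARD[1:20],
                 name = "WAG")
  tr <- randomTree(6, seed = 91)
  aln <- simAln(m, tr, 80, seed = 5)
  ph <- phangorn::phyDat(aln, type = "AA")
  fit <- phangorn::pml(tr, ph, model = "WAG")
  expect_equal(logLikelihood(aln, tr, m), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("gaps and unknown residues act as missing data", {
  m <- toyModel()
  tr <- readNewick(text = "(t1:0.2,t2:0.3);")
  aln <- matrix(c("a", "b", "a", "-", "?", "b"), 2, 3, byrow = FALSE,
                dimnames = list(c("t1", "t2"), NULL))
  ## column 2: t2 missing -> reduces to single-sequence likelihood over t1
  single <- matrix(c("a", "-"), 2, 1, dimnames = list(c("t1", "t2"), NULL))
  lnl <- logLikelihood(single, tr, m)
  gen <- buildGenerator(m)
  expect_equal(lnl, log(equilibriumFreqs(m)[1]), tolerance = 1e-12)
  expect_true(is.finite(logLikelihood(aln, tr, m)))
})

test_that("lnL stays finite for large trees with small branches", {
  m <- randomModel(seed = 101)
  tr <- randomTree(200, meanLength = 0.02, seed = 101)
  aln <- simAln(m, tr, 300, seed = 6)
  lnl <- logLikelihood(aln, tr, m, discreteGamma(0.5, 4))
  expect_true(is.finite(lnl))
})

test_that("the generating matrix outscores a distant matrix on its own data", {
  a <- randomModel(seed = 111, name = "A")
  b <- randomModel(seed = 222, name = "B")
  tr <- randomTree(12, seed = 11)
  aln <- simAln(a, tr, 500, seed = 7)
  expect_gt(logLikelihood(aln, tr, a), logLikelihood(aln, tr, b))
})

test_that("heterogeneity fitting recovers alpha and detects homogeneity", {
  a <- randomModel(seed = 131, name = "A")
  tr <- randomTree(16, seed = 13)
  ## data simulated at alpha = 0.5: the fitted alpha lands near it
  okAlpha <- 0L
  for (r in 1:5) {
    aln <- simAln(a, tr, 2000, seed = 130 + r, het = discreteGamma(0.5, 4))
    fit <- fitHeterogeneity(aln, tr, candidateSpec(a, gamma = TRUE))
    if (fit$alpha >= 0.35 && fit$alpha <= 0.70) okAlpha <- okAlpha + 1L
  }
  expect_gte(okAlpha, 4L)
  ## homogeneous data drives alpha to the large boundary region
  okBound <- 0L
  for (r in 1:5) {
    aln <- simAln(a, tr, 1000, seed = 230 + r)
    fit <- fitHeterogeneity(aln, tr, candidateSpec(a, gamma = TRUE))
    if (fit$alpha >= 10) okBound <- okBound + 1L
  }
  expect_gte(okBound, 4L)
  ## no flags: a single pruning pass
  plain <- fitHeterogeneity(simAln(a, tr, 100, seed = 9), tr, candidateSpec(a))
  expect_true(plain$converged)
  expect_true(is.na(plain$alpha) && is.na(plain$pInv))
})

test_that("BIC selection ranks candidates and breaks ties deterministically", {
  a <- randomModel(seed = 141, name = "A")
  b <- randomModel(seed = 242, name = "B")
  tr <- randomTree(12, seed = 14)
  aln <- simAln(a, tr, 600, seed = 10, het = discreteGamma(0.5, 4))
  cands <- list(candidateSpec(a), candidateSpec(a, gamma = TRUE),
                candidateSpec(b), candidateSpec(b, gamma = TRUE))
  res <- selectModel(aln, tr, cands)
  expect_equal(res$candidate[1], "A+G")
  expect_equal(res$rank, 1:4)
  ## BIC identity holds exactly for every reported candidate
  expect_equal(res$BIC, -2 * res$lnL + res$kpar * log(ncol(aln)))

  ## identical candidates tie and are ordered deterministically by name
  dup <- selectModel(aln, tr, list(candidateSpec(a), candidateSpec(a)))
  expect_equal(dup$BIC[1], dup$BIC[2])
  expect_equal(dup$rank, 1:2)

  ## +I on top of a fit with no invariant signal costs ~ln(n) in BIC
  resI <- selectModel(aln, tr, list(candidateSpec(a, gamma = TRUE),
                                    candidateSpec(a, gamma = TRUE, inv = TRUE)))
  dBIC <- resI$BIC[resI$candidate == "A+I+G"] - resI$BIC[resI$candidate == "A+G"]
  expect_lt(abs(dBIC - log(ncol(aln))), 0.5)

  expect_error(selectModel(aln, tr, cands[1]), "at least 2")
})
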