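test_that("Newick parsing and writing round trip exactly", {
  tr <- readNewick(text = "((A:0.1,B:0.2):0.05,C:0.3);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_setequal(round(tr$edge.length, 10), c(0.1, 0.2, 0.05, 0.3))
  expect_error(readNewick(text = "((A,B)"), "parse")
  expect_warning(tr0 <- readNewick(text = "((A,B),C);"), "branch lengths")
  expect_true(all(tr0$edge.length == 0))

  set.seed(4)
  for (i in 1:50) {
    t1 <- randomTree(sample(4:20, 1), seed = 4000 + i)
    t2 <- readNewick(text = writeNewick(t1))
    expect_equal(rfDistance(t1, t2), 0)
    expect_lt(max(abs(sort(t2$edge.length) - sort(t1$edge.length))), 1e-12)
  }
})

test_that("site rates follow the category distribution", {
  expect_equal(drawSiteRates(homogeneousRates(), 10), rep(1, 10))
  frozen <- applyInvariant(homogeneousRates(), 1)
  expect_equal(drawSiteRates(frozen, 10), rep(0, 10))

  het <- applyInvariant(discreteGamma(0.5, 4), 0.2)
  r <- drawSiteRates(het, 100000, seed = 1)
  emp <- vapply(seq_along(het@rates),
                function(c) mean(abs(r - het@rates[c]) < 1e-12), 0)
  sigma <- sqrt(het@probs * (1 - het@probs) / 100000)
  expect_true(all(abs(emp - het@probs) <= 3 * sigma))
})

test_that("zero-length branches copy the root; seeding is reproducible", {
  m <- randomModel(seed = 5)
  tr <- readNewick(text = "((A:0,B:0):0,C:0);")
  root <- paste(rep(aminoAcids(), 3), collapse = "")
  aln <- simulateAlignment(m, tr, rootSequence = root, seed = 1)[[1]]
  expect_true(all(apply(aln, 1, paste0, collapse = "") == root))

  tr2 <- readNewick(text = "((A:0.3,B:0.2):0.1,C:0.3);")
  a1 <- simulateAlignment(m, tr2, nSites = 200, seed = 7)[[1]]
  a2 <- simulateAlignment(m, tr2, nSites = 200, seed = 7)[[1]]
  a3 <- simulateAlignment(m, tr2, nSites = 200, seed = 8)[[1]]
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))

  ## replicates differ among themselves but reproduce across runs
  reps <- simulateAlignment(m, tr2, nSites = 100, replicates = 3, seed = 7)
  expect_false(identical(reps[[1]], reps[[2]]))
  expect_identical(reps[[1]],
                   simulateAlignment(m, tr2, nSites = 100, replicates = 3,
                                     seed = 7)[[1]])

  expect_error(simulateAlignment(m, tr2, rootSequence = "ZZZ", seed = 1),
               "alphabet")
  expect_error(simulateAlignment(m, tr2, seed = 1), "nSites")
})

test_that("single-branch transitions calibrate against P(t) bands", {
  ## small-alphabet version of the calibration (the full 20-state sweep is
  ## run under the acceptance suite): balanced root, t = 0.5, exact 99.73%
  ## binomial bands per (i, j) pair
  m <- randomToyModel(seed = 11, n = 4L)
  g <- buildGenerator(m)
  P <- probMatrix(transitionMatrix(g, 0.5))
  tr <- readNewick(text = "(A:0.5,B:0);")  # A evolves over t = 0.5, B copies
  nPer <- 5000L
  root <- rep(alphabet(m), each = nPer)
  aln <- simulateAlignment(m, tr, rootSequence = root, seed = 1)[[1]]
  lvl <- 2 * pnorm(3) - 1
  for (i in seq_along(alphabet(m))) {
    cnt <- table(factor(aln["A", root == alphabet(m)[i]], levels = alphabet(m)))
    for (j in seq_along(alphabet(m))) {
      lo <- qbinom((1 - lvl) / 2, nPer, P[i, j])
      hi <- qbinom(1 - (1 - lvl) / 2, nPer, P[i, j])
      expect_gte(cnt[j], lo)
      expect_lte(cnt[j], hi)
    }
  }
})

test_that("equilibrium-root composition matches f and is stationary", {
  m <- randomModel(seed = 21)
  tr <- readNewick(text = "(A:0.5,B:1.0);")
  aln <- simulateAlignment(m, tr, nSites = 50000, seed = 1)[[1]]
  f <- equilibriumFreqs(m)
  comp <- composition(aln, alphabet = aminoAcids())
  n <- 2 * 50000
  chisq <- n * sum((comp - f)^2 / f)
  p <- pchisq(chisq, df = 19, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("expected substitutions per branch equal the branch length", {
  ## on a scaled model the per-site change probability over t is
  ## 1 - sum_i f_i P_ii(t); observed change counts must sit in 3-sigma bands
  m <- randomModel(seed = 31)
  g <- buildGenerator(m)
  nSites <- 50000L
  for (t in c(0.1, 0.5, 1.0)) {
    tr <- readNewick(text = sprintf("(A:%g,B:0);", t))
    aln <- simulateAlignment(m, tr, nSites = nSites, seed = 1)[[1]]
    changed <- sum(aln["A", ] != aln["B", ])   # B copies the root
    pChange <- 1 - sum(equilibriumFreqs(m) *
                       diag(probMatrix(transitionMatrix(g, t))))
    expect_lt(abs(changed - nSites * pChange),
              3 * sqrt(nSites * pChange * (1 - pChange)))
  }
})

test_that("gamma heterogeneity inflates per-site dispersion; large alpha is homogeneous", {
  m <- randomModel(seed = 41)
  star <- paste0("(", paste(sprintf("T%d:0.3", 1:32), collapse = ","), ");")
  tr <- readNewick(text = star)
  root <- paste(rep(aminoAcids(), 40), collapse = "")   # 800 sites
  hetAln <- simulateAlignment(m, tr, rootSequence = root,
                              het = discreteGamma(0.25, 4), seed = 1)[[1]]
  homAln <- simulateAlignment(m, tr, rootSequence = root, seed = 1)[[1]]
  rootChars <- strsplit(root, "")[[1]]
  dispersion <- function(aln) {
    k <- colSums(aln != rep(rootChars, each = nrow(aln)))
    var(k) / mean(k)
  }
  ## ignoring among-site rate variation shrinks the dispersion of per-site
  ## change counts toward the single-binomial level
  expect_gt(dispersion(hetAln), dispersion(homAln))

  ## alpha -> large converges to the homogeneous model distributionally
  bigAln <- simulateAlignment(m, tr, rootSequence = root,
                              het = discreteGamma(1000, 4), seed = 1)[[1]]
  expect_lt(abs(dispersion(bigAln) - dispersion(homAln)), 0.35)
})

test_that("composition pools symbols and excludes gaps", {
  expect_equal(composition(matrix(c("A", "A", "A", "A"), 1), c("A", "R")),
               c(A = 1, R = 0))
  aln <- matrix(c("A", "-", "R", "R"), 2)
  expect_equal(sum(composition(aln)), 1)
  expect_equal(unname(composition(aln, c("A", "R"))), c(1 / 3, 2 / 3))
  expect_error(composition(matrix("-", 1, 1)), "empty")
})

test_that("alignment FASTA I/O round trips", {
  m <- randomModel(seed = 51)
  tr <- randomTree(5, seed = 51)
  aln <- simulateAlignment(m, tr, nSites = 40, seed = 2)[[1]]
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFastaAlignment(aln, f)
  back <- readFastaAlignment(f)
  expect_identical(back[rownames(aln), ], aln)
})
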