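test_that("PAML parsing transcribes a toy file and the equal-rates file", {
  m <- parsePaml(text = c("1.0", "2.0 3.0", "0.5 0.3 0.2"),
                 alphabet = toyAlphabet)
  expect_equal(exchangeabilities(m),
               matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, byrow = TRUE,
                      dimnames = list(toyAlphabet, toyAlphabet)))
  expect_equal(equilibriumFreqs(m), c(0.5, 0.3, 0.2))
  expect_false(isFrequencyFree(m))

  txt <- c(vapply(1:19, function(k) paste(rep("1.0", k), collapse = " "), ""),
           paste(rep("0.05", 20), collapse = " "))
  eq <- parsePaml(text = txt)
  expect_true(all(exchangeabilities(eq)[upper.tri(diag(20))] == 1))
  expect_equal(equilibriumFreqs(eq), rep(0.05, 20))
})

test_that("PAML write/parse round trip is exact on random models", {
  for (seed in 1:5) {
    m <- randomModel(seed = seed)
    back <- parsePaml(text = writePaml(m), name = modelName(m))
    expect_lt(max(abs(exchangeabilities(back) - exchangeabilities(m))), 1e-12)
    expect_lt(max(abs(equilibriumFreqs(back) - equilibriumFreqs(m))), 1e-12)
  }
  ## small alphabets round-trip too
  t3 <- toyModel()
  back <- parsePaml(text = writePaml(t3), alphabet = toyAlphabet)
  expect_equal(exchangeabilities(back), exchangeabilities(t3))
})

test_that("PAML parser rejects malformed and invalid input", {
  expect_error(parsePaml(text = c("1.0", "2.0", "0.5 0.3 0.2"),
                         alphabet = toyAlphabet), "row 2")
  expect_error(parsePaml(text = c("-1.0", "2.0 3.0", "0.5 0.3 0.2"),
                         alphabet = toyAlphabet), "egative")
  expect_error(parsePaml(text = c("1.0", "2.0 3.0", "0.5 0.3 0.4"),
                         alphabet = toyAlphabet), "frequencies")
  ## with-diagonal files are rejected, not guessed
  expect_error(parsePaml(text = c("0.0", "1.0 0.0", "2.0 3.0 0.0",
                                  "0.5 0.3 0.2"),
                         alphabet = toyAlphabet), "diagonal")
  ## mild rounding in frequencies is renormalized with a warning
  expect_warning(
    m <- parsePaml(text = c("1.0", "2.0 3.0", "0.5001 0.3 0.2"),
                   alphabet = toyAlphabet), "renormalizing")
  expect_equal(sum(equilibriumFreqs(m)), 1)
})

test_that("frequency-free files get a flagged uniform default", {
  m <- parsePaml(text = c("1.0", "2.0 3.0"), alphabet = toyAlphabet)
  expect_true(isFrequencyFree(m))
  expect_equal(equilibriumFreqs(m), rep(1 / 3, 3))
  ## partially present frequencies are an error, not a silent default
  expect_error(parsePaml(text = c("1.0", "2.0 3.0", "0.5 0.5"),
                         alphabet = toyAlphabet), "frequencies")
})

test_that("score matrices parse, reject asymmetry, and round trip", {
  syms <- c("a", "b", "c", "d")
  S <- matrix(-1, 4, 4) + 2 * diag(4)
  txt <- c(paste(syms, collapse = " "),
           vapply(1:4, function(i) paste(c(syms[i], S[i, ]), collapse = " "), ""))
  sm <- parseScore(text = txt)
  expect_s4_class(sm, "ScoreModel")
  expect_equal(unname(scoreMatrix(sm)), S)

  back <- parseScore(text = writeScore(sm))
  expect_equal(scoreMatrix(back), scoreMatrix(sm))

  bad <- txt
  bad[2] <- "a 1 5 -1 -1"   # S[1,2] != S[2,1]
  expect_error(parseScore(text = bad), "asymmetric")

  ## lower-triangular-with-diagonal layout
  tri <- c("1", "-1 1", "-1 -1 1")
  sm2 <- parseScore(text = tri, alphabet = toyAlphabet)
  expect_equal(unname(scoreMatrix(sm2)), matrix(-1, 3, 3) + 2 * diag(3))
})

test_that("no partially valid model escapes the parser", {
  ## every parsed model satisfies the RateModel validity contract
  for (seed in 1:10) {
    m <- parsePaml(text = writePaml(randomModel(seed = seed, frequencyConcentration = 0.5)))
    expect_true(validObject(m))
  }
})

makeCatalog <- function() {
  m <- function(s) randomModel(seed = s, name = paste0("m", s))
  sc <- ScoreModel(matrix(0, 20, 20), name = "sc1")
  list(
    ModelRecord(m(1), taxonomicGroup = "viral", year = 2011, authors = "Ab; Cd"),
    ModelRecord(m(2), taxonomicGroup = "viral", year = 2007, authors = "Ef"),
    ModelRecord(m(3), taxonomicGroup = "mitochondrial", year = 1996, authors = "Gh"),
    ModelRecord(m(4), taxonomicGroup = "nuclear_general", year = 2015, authors = "Ab"),
    ModelRecord(sc, taxonomicGroup = "viral", year = 2011, authors = "Ij"),
    ModelRecord(m(5), taxonomicGroup = "chloroplast", year = 2020, authors = "Kl"))
}

test_that("filterRecords matches a brute-force scan and composes", {
  recs <- makeCatalog()
  expect_identical(filterRecords(recs), recs)

  got <- filterRecords(recs, list(kind = "rate", taxonomic_group = "viral"))
  want <- Filter(function(r) r@kind == "rate" && r@taxonomicGroup == "viral", recs)
  expect_equal(vapply(got, modelName, ""), vapply(want, modelName, ""))
  expect_length(got, 2L)

  got <- filterRecords(recs, list(year_min = 2010))
  want <- Filter(function(r) r@year >= 2010, recs)
  expect_equal(vapply(got, modelName, ""), vapply(want, modelName, ""))

  ## filter composition: sequential filters == conjunction
  a <- filterRecords(filterRecords(recs, list(kind = "rate")),
                     list(year_min = 2000))
  b <- filterRecords(recs, list(kind = "rate", year_min = 2000))
  expect_equal(vapply(a, modelName, ""), vapply(b, modelName, ""))

  ## sorting by a single field
  sorted <- filterRecords(recs, sortBy = "year")
  expect_equal(vapply(sorted, function(r) r@year, 1L),
               sort(vapply(recs, function(r) r@year, 1L)))

  expect_error(filterRecords(recs, list(flavor = "x")), "unknown")
  expect_error(filterRecords(recs, sortBy = "flavor"), "sort")
})

test_that("catalog persistence round trips through disk", {
  recs <- makeCatalog()
  dir <- withr::local_tempdir()
  writeModelCatalog(recs, dir)
  back <- readModelCatalog(dir)
  expect_length(back, length(recs))
  expect_equal(vapply(back, modelName, ""), vapply(recs, modelName, ""))
  expect_equal(vapply(back, function(r) r@taxonomicGroup, ""),
               vapply(recs, function(r) r@taxonomicGroup, ""))
  i <- which(vapply(recs, function(r) r@kind, "") == "rate")[1]
  expect_lt(max(abs(exchangeabilities(back[[i]]@model) -
                    exchangeabilities(recs[[i]]@model))), 1e-12)
})
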