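## PAML-dialect model file I/O.
##
## The dialect is fixed: n-1 lower-triangular rows WITHOUT the diagonal (row k
## carries the k rates pairing symbol k+1 with symbols 1..k), then the n
## equilibrium frequencies on the following non-blank line(s). Blank lines and
## anything after the frequencies are ignored. Files that carry n rows (i.e.
## include the diagonal) are rejected with a message rather than guessed at.

.readInputLines <- function(file, text) {
  if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
      text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    return(text)
  }
  if (is.null(file)) .stopf("either 'file' or 'text' must be supplied")
  readLines(file, warn = FALSE)
}

## tokenize a line; returns character(0) for blank lines
.tokens <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

.numTokens <- function(toks) suppressWarnings(as.numeric(toks))

#' Read a substitution model in PAML format
#'
#' Parses the plain-text interchange format used to distribute empirical
#' amino-acid models: \code{n - 1} whitespace-delimited rows of the lower
#' triangle of the relative-rate matrix (no diagonal), followed by a line (or
#' lines) with the \code{n} equilibrium frequencies. Blank lines anywhere and
#' text after the frequencies are ignored. When the frequency block is absent
#' the model receives uniform frequencies and is flagged frequency-free (see
#' \code{\link{isFrequencyFree}}), so downstream analyses can exclude it.
#'
#' Frequencies whose sum deviates from 1 by at most 1e-3 (published rounding)
#' are renormalized with a warning; larger deviations are an error. Negative
#' rates or frequencies are an error, as are rows with the wrong entry count
#' (reported by row number) and files that include the matrix diagonal.
#'
#' @param file path to a model file.
#' @param text alternatively, the file contents as a character vector (or a
#'   single string with embedded newlines).
#' @param alphabet residue symbols fixing the matrix order; default the 20
#'   amino acids in PAML order.
#' @param name model name; defaults to the file base name.
#' @return A \linkS4class{RateModel}.
#' @seealso \code{\link{writePaml}}
#' @export
#' @examples
#' txt <- c("1.0", "2.0 3.0", "0.5 0.3 0.2")
#' parsePaml(text = txt, alphabet = c("a", "b", "c"))
parsePaml <- function(file = NULL, text = NULL, alphabet = aminoAcids(), name = NULL) {
  lines <- .readInputLines(file, text)
  if (is.null(name))
    name <- if (!is.null(file)) tools::file_path_sans_ext(basename(file)) else "model"
  n <- length(alphabet)
  toks <- lapply(lines, .tokens)
  toks <- toks[lengths(toks) > 0L]
  if (length(toks) < n - 1L)
    .stopf("expected %d matrix rows, found only %d non-blank lines", n - 1L, length(toks))

  M <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) {
    vals <- .numTokens(toks[[k]])
    if (anyNA(vals))
      .stopf("matrix row %d contains a non-numeric entry", k)
    if (length(vals) != k)
      .stopf("malformed matrix: row %d has %d entries, expected %d", k, length(vals), k)
    M[k + 1L, seq_len(k)] <- vals
  }
  if (any(M < 0)) .stopf("negative relative rate in matrix")
  M <- M + t(M)

  ## collect frequencies from the following numeric lines
  freq <- numeric(0)
  i <- n  # index into toks of the first post-matrix line
  while (i <= length(toks) && length(freq) < n) {
    vals <- .numTokens(toks[[i]])
    if (anyNA(vals)) break  # non-numeric trailer: stop collecting
    freq <- c(freq, vals)
    i <- i + 1L
  }
  freqFree <- FALSE
  if (length(freq) == 0L) {
    f <- rep(1 / n, n)
    freqFree <- TRUE
  } else if (length(freq) != n) {
    .stopf("expected %d frequencies, found %d", n, length(freq))
  } else {
    ## with-diagonal detection: the 'frequencies' we read would then be matrix
    ## row n (sum far from 1) and the true frequencies follow as numbers
    if (abs(sum(freq) - 1) > 1e-3) {
      nxt <- if (i <= length(toks)) .numTokens(toks[[i]]) else NA
      if (length(nxt) >= 1L && !anyNA(nxt))
        .stopf("matrix appears to include the diagonal (%d rows before frequencies); this dialect expects %d rows without it", n, n - 1L)
      .stopf("frequencies sum to %.6g, outside the tolerated [0.999, 1.001]", sum(freq))
    }
    if (any(freq < 0)) .stopf("negative frequency")
    if (abs(sum(freq) - 1) > 1e-8) {
      warning(sprintf("frequencies sum to %.8g; renormalizing", sum(freq)), call. = FALSE)
      freq <- freq / sum(freq)
    } else if (sum(freq) != 1) {
      freq <- freq / sum(freq)
    }
    f <- freq
  }
  RateModel(M, f, alphabet = alphabet, name = name, freqFree = freqFree)
}

#' Write a substitution model in PAML format
#'
#' Emits the lower-triangular rows (no diagonal) and one line of equilibrium
#' frequencies at full precision (\code{\%.17g}), so that
#' \code{parsePaml(writePaml(m))} reproduces \code{m} exactly. A trailing
#' annotation line records the symbol order; it lies after the frequencies and
#' is ignored by the parser.
#'
#' @param model a \linkS4class{RateModel}.
#' @param file optional path; when omitted the lines are returned only.
#' @return Invisibly, the character vector of lines.
#' @export
writePaml <- function(model, file = NULL) {
  stopifnot(is(model, "RateModel"))
  M <- model@M
  n <- nrow(M)
  rows <- vapply(2:n, function(i) paste(.fmt(M[i, seq_len(i - 1L)]), collapse = " "), "")
  lines <- c(rows, "", paste(.fmt(model@f), collapse = " "), "",
             paste("order:", paste(model@alphabet, collapse = " ")))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a substitution score matrix
#'
#' Accepts either a labeled square matrix (a header row of symbols, then one
#' labeled row per symbol) or a lower-triangular layout \emph{with} diagonal
#' (row k has k entries, symbol order supplied via \code{alphabet}).
#' Asymmetric square input is rejected exactly (tolerance 0).
#'
#' @inheritParams parsePaml
#' @return A \linkS4class{ScoreModel}.
#' @seealso \code{\link{writeScore}}
#' @export
parseScore <- function(file = NULL, text = NULL, alphabet = NULL, name = NULL) {
  lines <- .readInputLines(file, text)
  if (is.null(name))
    name <- if (!is.null(file)) tools::file_path_sans_ext(basename(file)) else "score"
  toks <- lapply(lines, .tokens)
  toks <- toks[lengths(toks) > 0L]
  if (length(toks) == 0L) .stopf("empty score matrix input")

  first <- .numTokens(toks[[1L]])
  if (anyNA(first)) {
    ## labeled square format
    syms <- toks[[1L]]
    n <- length(syms)
    if (length(toks) < n + 1L) .stopf("expected %d labeled rows after the header", n)
    S <- matrix(NA_real_, n, n, dimnames = list(syms, syms))
    for (k in seq_len(n)) {
      row <- toks[[k + 1L]]
      lab <- row[1L]
      if (!lab %in% syms) .stopf("row label '%s' not in the header symbols", lab)
      vals <- .numTokens(row[-1L])
      if (anyNA(vals) || length(vals) != n)
        .stopf("row '%s' must carry exactly %d numeric scores", lab, n)
      S[lab, ] <- vals
    }
    if (anyNA(S)) .stopf("missing symbols: not every header symbol has a row")
    if (!identical(S, t(S))) .stopf("score matrix is asymmetric")
    ScoreModel(S, alphabet = syms, name = name)
  } else {
    ## lower-triangular with diagonal
    if (is.null(alphabet)) alphabet <- aminoAcids()
    n <- length(alphabet)
    if (length(toks) < n) .stopf("expected %d triangular rows, found %d", n, length(toks))
    S <- matrix(0, n, n)
    for (k in seq_len(n)) {
      vals <- .numTokens(toks[[k]])
      if (anyNA(vals) || length(vals) != k)
        .stopf("malformed score matrix: row %d must carry %d entries", k, k)
      S[k, seq_len(k)] <- vals
    }
    S <- S + t(S) - diag(diag(S))
    ScoreModel(S, alphabet = alphabet, name = name)
  }
}

#' Write a substitution score matrix (labeled square format)
#'
#' @param model a \linkS4class{ScoreModel}.
#' @param file optional path.
#' @return Invisibly, the character vector of lines.
#' @export
writeScore <- function(model, file = NULL) {
  stopifnot(is(model, "ScoreModel"))
  S <- model@S
  lines <- c(paste(model@alphabet, collapse = " "),
             vapply(seq_len(nrow(S)), function(i)
               paste(c(model@alphabet[i], .fmt(S[i, ])), collapse = " "), ""))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
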