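#' The twenty amino acids in PAML order
#'
#' Returns the canonical one-letter amino-acid alphabet in the fixed order used
#' by PAML-format model files (ARNDCQEGHILKMFPSTWYV). All 20-state models in
#' the package index their matrices and frequency vectors by this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## full-precision number formatting used by every writer, so regenerated
## artifacts are byte-identical and round-trips are exact
.fmt <- function(x) sprintf("%.17g", x)

## evaluate expr under a given seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## counter-based derivation of per-replicate/per-artifact seeds from a master
## seed; kept below 2^31 - 1 so the result is a valid R integer seed
.deriveSeed <- function(seed, counter) {
  as.integer((as.double(seed) %% 2147483647 + 104729 * as.double(counter)) %% 2147483647)
}

## column maxima of a small-row matrix without apply() overhead
.colMax <- function(m) {
  out <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) out <- pmax.int(out, m[i, ])
  out
}

## log(sum(exp(x))) safe against -Inf columns; x is a k x p matrix, reduce rows
.logColSumExp <- function(x) {
  m <- .colMax(x)
  m[!is.finite(m)] <- 0
  m + log(colSums(exp(sweep(x, 2L, m, "-"))))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
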