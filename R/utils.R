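#' @importFrom stats rnorm runif median quantile pt sd setNames optim complete.cases
#' @importFrom utils write.table read.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the package; accepts
#' IUPAC degeneracy codes.
#'
#' @param x character scalar over IUPAC DNA codes.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## IUPAC code -> allowed base set (uppercase)
iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(strsplit(map, ""), identity)
}

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    nchar(x) >= 1L && !grepl("[^ACGT]", x)
}

## A unit is primitive when it is not a concatenation of a shorter repeat.
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0L &&
        paste(rep(substr(unit, 1L, d), k / d), collapse = "") == unit) {
      return(FALSE)
    }
  }
  TRUE
}

## Deterministic derivation of per-stream seeds from one root seed.
## Kept strictly below 2^31 so the result is a valid R integer.
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}

## uppercase, with optional soft-mask handling: lowercase bases either
## uppercased (default) or turned into run-breaking 'N's.
normalize_seq <- function(seq, respect_softmask = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (respect_softmask) seq <- gsub("[a-z]", "N", seq)
  toupper(seq)
}

## random i.i.d. background sequence with a given GC content
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## geometric mean
gmean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
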