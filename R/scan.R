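#' Microsatellite scanning
#'
#' EWSR1-FLI1 converts GGAA microsatellites -- maximal runs of consecutive
#' GGAA units -- into de novo enhancers, with detectable binding from 4
#' consecutive repeats upward. These functions locate every maximal run of a
#' repeat unit in a sequence or genome.
#'
#' @name msat-scanning
NULL

#' Specify a repeat unit
#'
#' @param unit DNA string over A/C/G/T, length >= 2, primitive (not itself a
#'   concatenation of a shorter repeat). Default \code{"GGAA"}.
#' @param min_repeats minimum number of complete consecutive copies for a run
#'   to be reported. Default 4, the threshold at which EWSR1-FLI1 binding of
#'   GGAA microsatellites becomes detectable.
#' @return an object of class \code{repeat_unit}.
#' @examples
#' repeat_unit()                 # GGAA, min 4
#' repeat_unit("CAG", 10)        # polyglutamine-style scan
#' @export
repeat_unit <- function(unit = "GGAA", min_repeats = 4L) {
  unit <- toupper(unit)
  if (!is_dna(unit) || nchar(unit) < 2L) {
    stop("`unit` must be a DNA string over A/C/G/T with length >= 2")
  }
  if (!is_primitive_unit(unit)) {
    stop("`unit` must be primitive, got a concatenation of a shorter repeat: ", unit)
  }
  min_repeats <- as.integer(min_repeats)
  if (is.na(min_repeats) || min_repeats < 1L) stop("`min_repeats` must be >= 1")
  structure(list(unit = unit, min_repeats = min_repeats), class = "repeat_unit")
}

## Maximal chains of complete unit copies in one (uppercase, normalized)
## sequence. Returns 0-based half-open starts/ends plus copy counts, before
## any min_repeats filtering. Phase conflicts (possible for generic units,
## impossible for GGAA) are resolved by keeping the chain with more complete
## copies, leftmost on ties, and dropping chains that overlap a kept one.
unit_chains <- function(seq, unit) {
  k <- nchar(unit)
  n <- nchar(seq)
  if (n < k) {
    return(data.frame(start = integer(), end = integer(), repeat_count = integer()))
  }
  m <- Biostrings::matchPattern(unit, Biostrings::DNAString(seq), fixed = TRUE)
  starts0 <- Biostrings::start(m) - 1L       # 0-based
  if (length(starts0) == 0L) {
    return(data.frame(start = integer(), end = integer(), repeat_count = integer()))
  }
  ## chain = arithmetic run of match starts with step k (same phase, abutting)
  brk <- c(TRUE, diff(starts0) != k)
  id <- cumsum(brk)
  first <- tapply(starts0, id, min)
  count <- as.integer(tapply(starts0, id, length))
  chains <- data.frame(start = as.integer(first),
                       end = as.integer(first + count * k),
                       repeat_count = count)
  ## greedy non-overlap selection: more copies first, then leftmost
  chains <- chains[order(-chains$repeat_count, chains$start), , drop = FALSE]
  keep <- logical(nrow(chains))
  taken_end <- integer(0); taken_start <- integer(0)
  for (i in seq_len(nrow(chains))) {
    s <- chains$start[i]; e <- chains$end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  chains <- chains[keep, , drop = FALSE]
  chains[order(chains$start), , drop = FALSE]
}

#' Scan one sequence for maximal repeat runs
#'
#' Finds every maximal run of complete, consecutive copies of the unit on the
#' given strand of \code{seq}. Only complete copies count; a flanking partial
#' copy does not extend a run. Any character outside A/C/G/T breaks a run.
#'
#' @param seq character scalar, DNA sequence. Lowercase (soft-masked) bases
#'   are uppercased unless \code{respect_softmask = TRUE}, in which case they
#'   break runs.
#' @param spec a \code{\link{repeat_unit}}.
#' @param respect_softmask treat lowercase bases as run breaks.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open) and \code{repeat_count}, sorted by start. Guarantees
#'   \code{end - start == repeat_count * nchar(unit)} and maximality: the unit
#'   does not recur immediately before \code{start} or after \code{end} in the
#'   run's reading frame.
#' @examples
#' scan_sequence(strrep("GGAA", 4))            # one hit, count 4
#' scan_sequence(strrep("GGAA", 3))            # below threshold: none
#' @export
scan_sequence <- function(seq, spec = repeat_unit(), respect_softmask = FALSE) {
  stopifnot(inherits(spec, "repeat_unit"))
  seq <- normalize_seq(seq, respect_softmask)
  seq <- gsub("[^ACGT]", "N", seq)
  hits <- unit_chains(seq, spec$unit)
  hits <- hits[hits$repeat_count >= spec$min_repeats, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a genome for repeat runs on both strands
#'
#' Plus-strand hits come from scanning the unit itself; minus-strand hits from
#' scanning its reverse complement on the forward sequence (for GGAA these are
#' the TTCC runs), reported in forward coordinates with strand \code{"-"}.
#' GGAA and TTCC records are kept separate; they cannot overlap.
#' Chromosomes are processed one at a time, so memory is bounded by the
#' largest chromosome.
#'
#' @param fasta path to a FASTA file, or a named \code{DNAStringSet} /
#'   named character vector of chromosome sequences.
#' @param spec a \code{\link{repeat_unit}}.
#' @param both_strands also scan the reverse-complement unit (default TRUE).
#'   Ignored (forward only) when the unit is its own reverse complement.
#' @param respect_softmask treat lowercase bases as run breaks.
#' @return BED-like data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{name} (\code{<unit>x<count>}),
#'   \code{score} (= repeat count) and \code{strand}, sorted by (chrom, start).
#' @export
scan_genome <- function(fasta, spec = repeat_unit(), both_strands = TRUE,
                        respect_softmask = FALSE) {
  stopifnot(inherits(spec, "repeat_unit"))
  seqs <- load_genome(fasta)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  rc <- revcomp(spec$unit)
  scan_minus <- both_strands && !identical(rc, spec$unit)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    fwd <- scan_sequence(s, spec, respect_softmask)
    fwd$strand <- if (nrow(fwd)) "+" else character(0)
    res <- fwd
    if (scan_minus) {
      rev <- scan_sequence(s, repeat_unit(rc, spec$min_repeats), respect_softmask)
      rev$strand <- if (nrow(rev)) "-" else character(0)
      res <- rbind(fwd, rev)
    }
    if (nrow(res)) {
      res <- data.frame(chrom = names(seqs)[i], start = res$start, end = res$end,
                        name = paste0(spec$unit, "x", res$repeat_count),
                        score = res$repeat_count, strand = res$strand,
                        stringsAsFactors = FALSE)
    } else {
      res <- empty_hit_table()
    }
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_hit_table <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

## Accept a path, DNAStringSet, or named character vector.
load_genome <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    return(Biostrings::readDNAStringSet(fasta))
  }
  if (methods::is(fasta, "DNAStringSet")) return(fasta)
  if (is.character(fasta) && !is.null(names(fasta))) {
    return(Biostrings::DNAStringSet(fasta))
  }
  stop("`fasta` must be a file path, DNAStringSet, or named character vector")
}
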