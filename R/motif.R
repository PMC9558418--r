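#' IUPAC consensus motif tools
#'
#' PAX3-FOXO1 binds the degenerate consensus ATTWGTCACGGT (W = A or T), whose
#' GTCACGGT core is necessary for super-enhancer activity. These functions
#' scan sequences for consensus matches with a mismatch budget, "repair"
#' near-matches to a perfect match with the minimal number of substitutions,
#' and count exact occurrences (the motif dose of a design).
#'
#' @name motif-tools
NULL

P3F1_CONSENSUS <- "ATTWGTCACGGT"

#' Build an IUPAC consensus
#'
#' @param pattern string over IUPAC codes, length >= 4.
#' @return object of class \code{iupac_consensus} carrying the per-position
#'   allowed base sets.
#' @examples
#' iupac_consensus("ATTWGTCACGGT")  # the PAX3-FOXO1 motif; W = A or T
#' @export
iupac_consensus <- function(pattern = P3F1_CONSENSUS) {
  pattern <- toupper(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) < 4L) stop("consensus must have length >= 4")
  sets <- iupac_sets()
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(chars, names(sets))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  structure(list(pattern = pattern, expansion = sets[chars]),
            class = "iupac_consensus")
}

as_consensus <- function(x) {
  if (inherits(x, "iupac_consensus")) x else iupac_consensus(x)
}

## reverse-complement a consensus (complement sets, reverse order)
revcomp_consensus <- function(cons) {
  iupac_consensus(revcomp(cons$pattern))
}

## mismatch counts of every window of seq against the consensus sets;
## returns integer vector of length nchar(seq) - k + 1 (or length 0).
window_mismatches <- function(seq, cons) {
  k <- nchar(cons$pattern)
  n <- nchar(seq)
  if (n < k) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  nwin <- n - k + 1L
  mm <- integer(nwin)
  for (j in seq_len(k)) {
    mm <- mm + !(chars[j:(j + nwin - 1L)] %in% cons$expansion[[j]])
  }
  mm
}

#' Scan a sequence for consensus matches
#'
#' Exhaustive window scan on both strands. A mismatch is a position whose
#' base falls outside the consensus' allowed set; minus-strand windows are
#' compared against the reverse-complemented consensus and reported at
#' forward coordinates with strand \code{"-"}. Overlapping windows are
#' reported individually.
#'
#' @param seq uppercase DNA string.
#' @param consensus an \code{\link{iupac_consensus}} or pattern string.
#' @param max_mismatch maximum mismatches per reported window, >= 0.
#' @param both_strands scan the minus strand too (default TRUE).
#' @return data.frame with \code{pos} (0-based offset of the window on the
#'   forward sequence), \code{strand}, \code{mismatches}, \code{matched_seq}
#'   (forward-strand window), sorted by pos then strand.
#' @export
match_consensus <- function(seq, consensus = P3F1_CONSENSUS, max_mismatch = 0L,
                            both_strands = TRUE) {
  cons <- as_consensus(consensus)
  stopifnot(max_mismatch >= 0L)
  seq <- toupper(seq)
  k <- nchar(cons$pattern)
  res <- list()
  mmf <- window_mismatches(seq, cons)
  if (length(mmf)) {
    sel <- which(mmf <= max_mismatch)
    if (length(sel)) {
      res[["+"]] <- data.frame(pos = sel - 1L, strand = "+",
                               mismatches = mmf[sel],
                               stringsAsFactors = FALSE)
    }
  }
  if (both_strands) {
    mmr <- window_mismatches(seq, revcomp_consensus(cons))
    sel <- which(mmr <= max_mismatch)
    if (length(sel)) {
      res[["-"]] <- data.frame(pos = sel - 1L, strand = "-",
                               mismatches = mmr[sel],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(pos = integer(), strand = character(),
                      mismatches = integer(), matched_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  out$matched_seq <- substring(seq, out$pos + 1L, out$pos + k)
  rownames(out) <- NULL
  out
}

#' Repair a near-match to a perfect consensus match
#'
#' Substitutes the minimal number of bases inside the matched window so it
#' matches the consensus with zero mismatches. Positions already compatible
#' (including at degenerate positions) are untouched; where a change is
#' needed at a degenerate position, the alphabetically first allowed base is
#' used. For a minus-strand match the window is repaired against the
#' reverse-complemented consensus, so the choice is alphabetically first in
#' forward-strand coordinates.
#'
#' @param seq DNA string containing the window.
#' @param match one row of \code{\link{match_consensus}} output (or a list
#'   with \code{pos} and \code{strand}).
#' @param consensus the consensus the window should match.
#' @return list with \code{seq} (edited full sequence), \code{edits}
#'   (number of substitutions, equal to the window's prior mismatch count)
#'   and \code{window} (the repaired window).
#' @export
repair_to_consensus <- function(seq, match, consensus = P3F1_CONSENSUS) {
  cons <- as_consensus(consensus)
  seq <- toupper(seq)
  k <- nchar(cons$pattern)
  pos <- as.integer(match$pos)
  strand <- as.character(match$strand %||% "+")
  if (is.na(pos) || pos < 0L || pos + k > nchar(seq)) {
    stop("match window [", pos, ", ", pos + k, ") out of bounds for sequence of length ",
         nchar(seq))
  }
  eff <- if (strand == "-") revcomp_consensus(cons) else cons
  chars <- strsplit(substring(seq, pos + 1L, pos + k), "")[[1]]
  edits <- 0L
  for (j in seq_len(k)) {
    allowed <- eff$expansion[[j]]
    if (!(chars[j] %in% allowed)) {
      chars[j] <- sort(allowed)[1L]
      edits <- edits + 1L
    }
  }
  window <- paste(chars, collapse = "")
  list(seq = paste0(substr(seq, 1L, pos), window,
                    substring(seq, pos + k + 1L)),
       edits = edits, window = window)
}

#' Count exact consensus matches on both strands
#'
#' Zero-mismatch windows over both strands; overlapping occurrences count
#' individually. This is the "motif dose" used to verify multimerized
#' designs (e.g. syn_alk_5 carries five more exact ATTWGTCACGGT matches than
#' syn_alk).
#'
#' @param seq DNA string.
#' @param consensus consensus pattern or \code{\link{iupac_consensus}}.
#' @return integer count.
#' @export
count_exact_matches <- function(seq, consensus = P3F1_CONSENSUS) {
  nrow(match_consensus(seq, consensus, max_mismatch = 0L))
}
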