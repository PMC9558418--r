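# Independent oracles and fixture builders used across the suite.
# Each oracle deliberately takes a different algorithmic route from the
# package implementation it checks.

# Regex oracle for maximal repeat runs: greedy `(unit){min,}` with a
# maximality post-check on the flanks. 0-based half-open output.
oracle_scan_regex <- function(seq, unit = "GGAA", min_repeats = 4L) {
  seq <- toupper(seq)
  k <- nchar(unit)
  pat <- paste0("(?:", unit, "){", min_repeats, ",}")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      repeat_count = integer()))
  }
  start1 <- as.integer(m)
  len <- attr(m, "match.length")
  out <- data.frame(start = start1 - 1L, end = start1 - 1L + len,
                    repeat_count = as.integer(len / k))
  # maximality post-check: no complete unit copy immediately before/after
  ok <- vapply(seq_len(nrow(out)), function(i) {
    s <- out$start[i]; e <- out$end[i]
    before <- if (s >= k) substring(seq, s - k + 1L, s) else ""
    after <- substring(seq, e + 1L, e + k)
    before != unit && after != unit
  }, logical(1))
  stopifnot(all(ok))   # greedy regex should already be maximal
  out
}

# Quadratic all-pairs overlap oracle for bound flagging.
oracle_flag_bound <- function(hits, peaks, min_overlap = 1L) {
  vapply(seq_len(nrow(hits)), function(i) {
    any(vapply(seq_len(nrow(peaks)), function(j) {
      if (hits$chrom[i] != peaks$chrom[j]) return(FALSE)
      ov <- min(hits$end[i], peaks$end[j]) - max(hits$start[i], peaks$start[j])
      ov >= min_overlap
    }, logical(1)))
  }, logical(1))
}

# Per-window Hamming-against-sets oracle for consensus matching, both strands.
oracle_match_consensus <- function(seq, pattern, max_mismatch) {
  seq <- toupper(seq)
  sets <- lapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""), identity)
  mm_of <- function(window, pat_chars) {
    w <- strsplit(window, "")[[1]]
    sum(vapply(seq_along(w), function(j) !(w[j] %in% sets[[pat_chars[j]]]),
               logical(1)))
  }
  k <- nchar(pattern)
  res <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "-") revcomp(pattern) else pattern
    pat_chars <- strsplit(pat, "")[[1]]
    for (p in seq_len(max(nchar(seq) - k + 1L, 0L))) {
      w <- substring(seq, p, p + k - 1L)
      mm <- mm_of(w, pat_chars)
      if (mm <= max_mismatch) {
        res <- rbind(res, data.frame(pos = p - 1L, strand = strand,
                                     mismatches = mm, matched_seq = w,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(res)) {
    return(data.frame(pos = integer(), strand = character(),
                      mismatches = integer(), matched_seq = character(),
                      stringsAsFactors = FALSE))
  }
  res <- res[order(res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random test sequence with occasional spliced-in repeat runs so the run
# density is high enough to exercise the scanner.
random_test_seq <- function(len = 200L, run_prob = 0.6) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.3, 0.2)), collapse = "")
  if (runif(1) < run_prob) {
    n <- sample(1:8, 1L)
    at <- sample.int(len - 4L * n, 1L)
    s <- paste0(substr(s, 1L, at), strrep("GGAA", n),
                substring(s, at + 4L * n + 1L))
  }
  s
}

# ~300 bp synthetic stand-in for the ALK intron-3 enhancer segment (the
# published coordinates chr2:29,657,671-29,657,976 name a region, not a
# printed sequence) carrying one near-match of the PAX3-FOXO1 consensus
# with exactly two mismatches in the GTCACGGT core.
synthetic_alk_base <- function(seed = 42L) {
  set.seed(seed)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE),
               collapse = "")
    # degrade the exact ATTAGTCACGGT: core C->G at position 8, T->A at 12
    near <- "ATTAGTCGCGGA"
    s <- paste0(substr(s, 1L, 150L), near, substring(s, 163L))
    if (count_exact_matches(s) == 0L &&
        nrow(scan_sequence(s)) == 0L &&
        nrow(match_consensus(s, max_mismatch = 2L)) == 1L) {
      return(s)
    }
  }
}
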