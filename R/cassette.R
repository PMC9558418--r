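#' Synthetic expression-cassette design
#'
#' The therapeutic designs pair a fusion-oncoprotein-responsive enhancer
#' block with a minimal promoter and P2A-linked payload open reading frames:
#' GGAA-repeat blocks (17/21/25 copies; 25 is the strongest within the
#' optimal 15-25 binding band) directly upstream of a YB-TATA-class minimal
#' promoter for EWSR1-FLI1, and a repaired/multimerized ATTWGTCACGGT enhancer
#' for PAX3-FOXO1. Assembly is guarded: junctions must not create or extend
#' repeat runs or consensus motifs beyond what the design specifies.
#'
#' The published constructs' exact YB-TATA, P2A, and payload sequences are
#' not printed; the defaults shipped here are clearly-labelled synthetic
#' stand-ins with the right structural properties (TATA-containing minimal
#' promoter, standard P2A peptide, valid ORFs), all overridable. The engine's
#' contracts are sequence-agnostic.
#'
#' @name cassette-design
NULL

#' Construct a cassette part
#'
#' @param name part name.
#' @param role one of enhancer, spacer, min_promoter, kozak, orf, linker.
#' @param sequence DNA string; may be empty only for spacers.
#' @export
cassette_part <- function(name, role, sequence) {
  roles <- c("enhancer", "spacer", "min_promoter", "kozak", "orf", "linker")
  role <- match.arg(role, roles)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L && role != "spacer") {
    stop("empty sequence only allowed for spacer parts")
  }
  if (nchar(sequence) > 0L && !is_dna(sequence)) {
    stop("part sequence must be DNA over A/C/G/T: ", name)
  }
  structure(list(name = name, role = role, sequence = sequence),
            class = "cassette_part")
}

## -- synthetic default parts ------------------------------------------------
## All placeholder sequences below are synthetic stand-ins (the published
## plasmid sequences are not printed); chosen to contain no GGAA run and no
## exact ATTWGTCACGGT match on either strand (asserted in the test suite).

#' Default synthetic parts for cassette assembly
#'
#' \code{yb_tata_promoter}: synthetic TATA-containing minimal promoter
#' stand-in for YB-TATA. \code{p2a_linker}: standard P2A self-cleaving
#' peptide coding sequence (66 nt, one reading frame). \code{kozak_part}:
#' GCCACC. \code{default_payloads}: two synthetic ORF stand-ins mimicking the
#' suicide-gene + reporter bicistron (first ORF stop-free, second carrying
#' the single terminal stop).
#' @name default-parts
NULL

#' @rdname default-parts
#' @export
yb_tata_promoter <- function() {
  cassette_part("YB-TATA_synthetic", "min_promoter",
                "AGAGGGTATATAATGGGTCCCGCAGTC")
}

#' @rdname default-parts
#' @export
p2a_linker <- function() {
  cassette_part("P2A", "linker",
                paste0("GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGAGACGTG",
                       "GAGGAGAACCCTGGACCT"))
}

#' @rdname default-parts
#' @export
kozak_part <- function() cassette_part("kozak", "kozak", "GCCACC")

#' @rdname default-parts
#' @export
default_payloads <- function() {
  list(
    cassette_part("HSV-TK_stub_synthetic", "orf",
                  paste0("ATG", "GCTCATCTGTCCGTCAAGCGTTGCATCGAT")),
    cassette_part("Fluc_stub_synthetic", "orf",
                  paste0("ATG", "TTCCTGAGCGTTCACTGTCGATTGAAC", "TAA"))
  )
}

neutral_spacer <- function(n = 10L) {
  stopifnot(n >= 1L)
  base <- "CTCGTCTCAC"
  cassette_part(paste0("spacer", n), "spacer",
                substr(strrep(base, ceiling(n / nchar(base))), 1L, n))
}

assemble <- function(parts) {
  seqs <- vapply(parts, function(p) p$sequence, character(1))
  lens <- nchar(seqs)
  assembled <- paste(seqs, collapse = "")
  ends <- cumsum(lens)
  starts <- ends - lens
  keep <- lens > 0L
  features <- data.frame(
    name = vapply(parts, function(p) p$name, character(1))[keep],
    role = vapply(parts, function(p) p$role, character(1))[keep],
    start = as.integer(starts[keep]), end = as.integer(ends[keep]),
    stringsAsFactors = FALSE)
  structure(list(parts = parts, assembled = assembled, features = features),
            class = "cassette_design")
}

#' @export
print.cassette_design <- function(x, ...) {
  cat("cassette_design:", nchar(x$assembled), "bp,",
      nrow(x$features), "features\n")
  print(x$features, ...)
  invisible(x)
}

feature_at <- function(design, pos) {
  f <- design$features
  hit <- f$start <= pos & f$end > pos
  if (!any(hit)) "end-of-assembly" else paste(f$name[hit], collapse = "/")
}

#' Design a GGAA-repeat expression cassette
#'
#' Assembles \code{[GGAA x n][spacer][minimal promoter][kozak][ORF1][linker]
#' [ORF2]...}. "Directly upstream" is a 0-bp default spacer; if the junction
#' would create or extend a repeat run (e.g. a promoter starting with GGAA),
#' a 1-bp neutral spacer is inserted automatically when
#' \code{auto_spacer = TRUE}, otherwise the junction is reported as an error.
#' The junction guard re-scans the full assembly: it must contain exactly one
#' microsatellite of \code{n_repeats} copies when \code{n_repeats} is at or
#' above the scan threshold, and none at all below it (the repeat-free
#' control design).
#'
#' @param n_repeats number of GGAA copies, >= 0 (0 = control cassette).
#' @param min_promoter,payloads,linker,kozak cassette parts; defaults are the
#'   synthetic stand-ins (\code{\link{yb_tata_promoter}} etc.).
#' @param unit repeat unit (default GGAA).
#' @param min_repeats scanner threshold used by the junction guard.
#' @param auto_spacer insert a 1-bp neutral spacer when the enhancer/promoter
#'   junction would break the guard.
#' @return a \code{cassette_design}.
#' @examples
#' d <- design_ggaa_cassette(25)
#' scan_sequence(d$assembled)   # one hit, 25 copies, 100 bp
#' @export
design_ggaa_cassette <- function(n_repeats,
                                 min_promoter = yb_tata_promoter(),
                                 payloads = default_payloads(),
                                 linker = p2a_linker(),
                                 kozak = kozak_part(),
                                 unit = "GGAA", min_repeats = 4L,
                                 auto_spacer = TRUE) {
  n_repeats <- as.integer(n_repeats)
  stopifnot(n_repeats >= 0L)
  check_payloads(payloads, linker)
  enh <- if (n_repeats > 0L) {
    list(cassette_part(paste0(unit, "x", n_repeats), "enhancer",
                       strrep(unit, n_repeats)))
  } else list()   # repeat-free control cassette
  build <- function(spacer_parts) {
    assemble(c(enh, spacer_parts, list(min_promoter, kozak),
               interleave_linker(payloads, linker)))
  }
  design <- build(list())
  err <- ggaa_guard_error(design, n_repeats, unit, min_repeats)
  if (!is.null(err) && auto_spacer) {
    design <- build(list(cassette_part("junction_spacer", "spacer", "C")))
    err <- ggaa_guard_error(design, n_repeats, unit, min_repeats)
  }
  if (!is.null(err)) stop("junction guard: ", err)
  design
}

check_payloads <- function(payloads, linker) {
  if (!length(payloads)) stop("at least one payload ORF required")
  for (p in payloads) {
    if (p$role != "orf") stop("payloads must have role 'orf'")
    if (substr(p$sequence, 1L, 3L) != "ATG") {
      stop("payload ORF must start with ATG: ", p$name)
    }
  }
  if (nchar(linker$sequence) %% 3L != 0L) {
    stop("linker length must be divisible by 3 to preserve the reading frame")
  }
}

interleave_linker <- function(payloads, linker) {
  out <- list()
  for (i in seq_along(payloads)) {
    out <- c(out, list(payloads[[i]]))
    if (i < length(payloads)) out <- c(out, list(linker))
  }
  out
}

ggaa_guard_error <- function(design, n_repeats, unit, min_repeats) {
  hits <- scan_sequence(design$assembled, repeat_unit(unit, min_repeats))
  if (n_repeats >= min_repeats) {
    if (nrow(hits) == 1L && hits$repeat_count[1L] == n_repeats) return(NULL)
  } else if (nrow(hits) == 0L) {
    return(NULL)
  }
  bad <- if (nrow(hits)) hits[which.max(hits$repeat_count), ] else NULL
  if (is.null(bad)) {
    return("expected one repeat run but the assembly contains none")
  }
  sprintf("assembly creates/extends a %dx%s run at [%d,%d) near feature(s) %s",
          bad$repeat_count, unit, bad$start, bad$end,
          feature_at(design, bad$start))
}

#' Design a motif-repaired / multimerized enhancer cassette
#'
#' Models the syn_alk family: the base enhancer (e.g. the ~300 bp
#' PAX3-FOXO1-bound segment from ALK intron 3, chr2:29,657,671-29,657,976 in
#' hg38, supplied by the user as sequence) is optionally "repaired" so that
#' its best near-match becomes a perfect consensus match (syn_alk), and
#' \code{extra_motifs} exact consensus copies are appended 5' of the base
#' enhancer separated by a neutral spacer (syn_alk_3, syn_alk_5). At
#' degenerate consensus positions the appended copies use the alphabetically
#' first allowed base. Junction guards re-count motifs on the assembly
#' (must equal the processed base's count plus \code{extra_motifs}) and
#' verify no repeat run at or above the scan threshold was created.
#'
#' @param base_enhancer DNA string, the enhancer to optimize.
#' @param repair repair the best (fewest mismatches, then leftmost)
#'   near-match of the consensus to a perfect match.
#' @param extra_motifs number of additional exact consensus copies, >= 0.
#' @param consensus IUPAC consensus (default ATTWGTCACGGT).
#' @param max_mismatch near-match budget used when \code{repair = TRUE}.
#' @param motif_spacer spacer part between appended motifs and before the
#'   base enhancer (default 10 bp neutral).
#' @param min_promoter,payloads,linker,kozak as in
#'   \code{\link{design_ggaa_cassette}}.
#' @param unit,min_repeats repeat-run guard parameters.
#' @return a \code{cassette_design}.
#' @export
design_p3f1_cassette <- function(base_enhancer, repair = TRUE,
                                 extra_motifs = 0L,
                                 consensus = P3F1_CONSENSUS,
                                 max_mismatch = 2L,
                                 motif_spacer = neutral_spacer(10L),
                                 min_promoter = yb_tata_promoter(),
                                 payloads = default_payloads(),
                                 linker = p2a_linker(),
                                 kozak = kozak_part(),
                                 unit = "GGAA", min_repeats = 4L) {
  extra_motifs <- as.integer(extra_motifs)
  stopifnot(extra_motifs >= 0L)
  cons <- as_consensus(consensus)
  check_payloads(payloads, linker)
  base_enhancer <- toupper(base_enhancer)
  base <- base_enhancer
  if (repair) {
    m <- match_consensus(base, cons, max_mismatch = max_mismatch)
    if (nrow(m) == 0L) {
      stop("repair requested but no match of ", cons$pattern, " within ",
           max_mismatch, " mismatches in the base enhancer")
    }
    m <- m[order(m$mismatches, m$pos, m$strand), , drop = FALSE]
    base <- repair_to_consensus(base, m[1L, ], cons)$seq
  }
  base_count <- count_exact_matches(base, cons)
  exact_motif <- paste(vapply(cons$expansion, function(s) sort(s)[1L],
                              character(1)), collapse = "")
  motif_parts <- list()
  for (i in seq_len(extra_motifs)) {
    motif_parts <- c(motif_parts,
                     list(cassette_part(paste0("motif", i), "enhancer",
                                        exact_motif),
                          motif_spacer))
  }
  base_part <- cassette_part("base_enhancer", "enhancer", base)
  parts <- c(motif_parts, list(base_part, min_promoter, kozak),
             interleave_linker(payloads, linker))
  design <- assemble(parts)
  got <- count_exact_matches(design$assembled, cons)
  if (got != base_count + extra_motifs) {
    stop("junction guard: assembly has ", got, " exact ", cons$pattern,
         " matches, expected ", base_count + extra_motifs)
  }
  base_runs <- scan_sequence(base, repeat_unit(unit, min_repeats))
  asm_runs <- scan_sequence(design$assembled, repeat_unit(unit, min_repeats))
  if (nrow(asm_runs) != nrow(base_runs) ||
      !identical(sort(asm_runs$repeat_count), sort(base_runs$repeat_count))) {
    stop("junction guard: assembly creates a ", unit,
         " run absent from the base enhancer")
  }
  design
}

#' Validate an assembled cassette
#'
#' @param design a \code{cassette_design}.
#' @param consensus motif whose exact matches are counted.
#' @param unit,min_repeats repeat-scan parameters.
#' @return machine-readable report: repeat runs found, exact motif count,
#'   reading-frame check across P2A linkers (single frame, single terminal
#'   stop), feature-tiling check, and an overall \code{pass} flag.
#' @export
validate_design <- function(design, consensus = P3F1_CONSENSUS,
                            unit = "GGAA", min_repeats = 4L) {
  stopifnot(inherits(design, "cassette_design"))
  f <- design$features
  msats <- scan_sequence(design$assembled, repeat_unit(unit, min_repeats))
  motif_n <- count_exact_matches(design$assembled, consensus)

  ## feature tiling: contiguous, gap-free cover of the assembly
  tiling_ok <- nrow(f) > 0L && f$start[1L] == 0L &&
    all(utils::head(f$end, -1L) == utils::tail(f$start, -1L)) &&
    f$end[nrow(f)] == nchar(design$assembled)

  ## reading frame: from the first ORF through the last ORF (including any
  ## linkers in between) must be one frame with a single terminal stop
  orf_rows <- which(f$role == "orf")
  frame <- list(ok = FALSE, message = "no ORF features")
  if (length(orf_rows) > 0L) {
    cds_start <- f$start[orf_rows[1L]]
    cds_end <- f$end[orf_rows[length(orf_rows)]]
    cds <- substring(design$assembled, cds_start + 1L, cds_end)
    if (nchar(cds) %% 3L != 0L) {
      frame <- list(ok = FALSE,
                    message = sprintf(
                      "CDS [%d,%d) length %d not divisible by 3",
                      cds_start, cds_end, nchar(cds)))
    } else if (substr(cds, 1L, 3L) != "ATG") {
      frame <- list(ok = FALSE, message = "CDS does not start with ATG")
    } else {
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
      stops <- gregexpr("\\*", aa)[[1L]]
      stops <- stops[stops > 0L]
      internal <- stops[stops < nchar(aa)]
      if (length(internal)) {
        frame <- list(ok = FALSE,
                      message = sprintf(
                        "internal stop codon at assembly position %d",
                        cds_start + (internal[1L] - 1L) * 3L))
      } else if (length(stops) != 1L) {
        frame <- list(ok = FALSE, message = "missing terminal stop codon")
      } else {
        frame <- list(ok = TRUE, message = "single frame, terminal stop only")
      }
    }
  }
  report <- list(
    length_bp = nchar(design$assembled),
    msat_runs = msats,
    n_msat_runs = nrow(msats),
    msat_max_repeats = if (nrow(msats)) max(msats$repeat_count) else 0L,
    exact_motif_count = motif_n,
    frame_check = frame,
    tiling_ok = tiling_ok)
  report$pass <- frame$ok && tiling_ok
  report
}

#' Score a GGAA enhancer block by repeat count
#'
#' EWSR1-FLI1 binding requires at least 4 consecutive GGAA repeats and is
#' optimal between 15 and 25 repeats.
#'
#' @param repeat_count integer >= 0.
#' @return list with \code{repeat_count}, \code{meets_threshold} (>= 4),
#'   \code{in_optimal_band} (15-25 inclusive), \code{band}.
#' @export
score_enhancer <- function(repeat_count) {
  repeat_count <- as.integer(repeat_count)
  stopifnot(repeat_count >= 0L)
  list(repeat_count = repeat_count,
       meets_threshold = repeat_count >= 4L,
       in_optimal_band = repeat_count >= 15L && repeat_count <= 25L,
       band = c(15L, 25L))
}

#' Write a cassette as a GenBank-style flat file
#'
#' Minimal single-record flat file (LOCUS/FEATURES/ORIGIN) with one
#' misc_feature per part; coordinates 1-based closed as GenBank requires.
#'
#' @param design a \code{cassette_design}.
#' @param path output path.
#' @param name locus name.
#' @export
write_cassette_genbank <- function(design, path, name = "cassette") {
  stopifnot(inherits(design, "cassette_design"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nchar(design$assembled)
  writeLines(sprintf("LOCUS       %s %d bp DNA linear SYN", name, n), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(design$features))) {
    f <- design$features[i, ]
    writeLines(sprintf("     misc_feature    %d..%d", f$start + 1L, f$end), con)
    writeLines(sprintf("                     /label=\"%s\"", f$name), con)
    writeLines(sprintf("                     /note=\"role:%s\"", f$role), con)
  }
  writeLines("ORIGIN", con)
  i <- 1L
  while (i <= n) {
    chunk <- substring(design$assembled, i, min(i + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, tolower(paste(blocks, collapse = " "))), con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}
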