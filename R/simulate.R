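#' Seeded synthetic-data generators
#'
#' Every input the pipeline consumes can be generated with machine-readable
#' ground truth: a genome with planted repeat runs, gene models that pin
#' microsatellites into requested genomic contexts, ChIP-style peaks covering
#' a controlled fraction of runs, a tumor-versus-normal expression matrix
#' with planted overexpressed genes (default dimensions 50 tumors versus 928
#' normal samples across 70 tissue types), and three-parameter log-logistic
#' dose-response curves with Gaussian noise. One root seed deterministically
#' derives independent per-generator substreams; identical (config, seed)
#' gives byte-identical files.
#'
#' @name synthetic-data
NULL

## letters usable as a one-base run breaker for a unit (never part of a copy)
breaker_base <- function(unit) {
  cand <- setdiff(DNA_BASES, strsplit(unit, "")[[1]])
  if (!length(cand)) {
    stop("unit uses all four bases; cannot guarantee a run breaker")
  }
  cand[1L]
}

#' Generate a genome with planted repeat runs
#'
#' Background is i.i.d. with configurable GC content. Each planted run is
#' written verbatim at its coordinates (reverse-complemented unit for minus
#' strand runs) and flanked by a one-base breaker drawn from outside the
#' unit's letter set, so background can never extend a planted run and the
#' recorded truth matches an exhaustive scan exactly. Accidental runs
#' arising in the background are not suppressed; they are recorded by an
#' exhaustive oracle scan at \code{min_repeats = 1}.
#'
#' @param chrom_lengths named integer vector, bp per chromosome.
#' @param planted data.frame with \code{chrom}, \code{start} (0-based),
#'   \code{repeat_count}, \code{strand}; may have zero rows.
#' @param seed integer root seed.
#' @param unit repeat unit (default GGAA).
#' @param gc background GC fraction.
#' @param out_dir if given, writes \code{genome.fa} plus truth sidecars
#'   (\code{genome_truth.json}, \code{planted_runs.tsv}).
#' @return list with \code{seqs} (named character vector) and \code{truth}:
#'   \code{planted_runs}, \code{accidental_runs} (both chrom/start/end/
#'   strand/repeat_count, 0-based half-open), \code{genome_length},
#'   \code{gc_content}, \code{unit}.
#' @export
make_genome <- function(chrom_lengths, planted = NULL, seed = 1L,
                        unit = "GGAA", gc = 0.41, out_dir = NULL) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  unit <- toupper(unit)
  k <- nchar(unit)
  if (is.null(planted)) {
    planted <- data.frame(chrom = character(), start = integer(),
                          repeat_count = integer(), strand = character())
  }
  stopifnot(all(c("chrom", "start", "repeat_count", "strand") %in% names(planted)))
  planted$end <- planted$start + planted$repeat_count * k
  if (any(planted$repeat_count < 1L)) stop("planted repeat_count must be >= 1")
  if (!all(planted$chrom %in% names(chrom_lengths))) {
    stop("planted run on unknown chromosome")
  }
  ## margins: one breaker base each side must fit
  bad <- planted$start < 1L | planted$end + 1L > chrom_lengths[planted$chrom]
  if (any(bad)) {
    stop("planted run out of bounds (need 1 bp breaker margin): row ",
         which(bad)[1L])
  }
  ## reject overlapping planted runs, reporting the colliding pair
  if (nrow(planted) > 1L) {
    o <- order(planted$chrom, planted$start)
    ps <- planted[o, ]
    same <- ps$chrom[-1L] == ps$chrom[-nrow(ps)]
    coll <- which(same & ps$start[-1L] < ps$end[-nrow(ps)])
    if (length(coll)) {
      i <- coll[1L]
      stop(sprintf("overlapping planted runs: %s:[%d,%d) and %s:[%d,%d)",
                   ps$chrom[i], ps$start[i], ps$end[i],
                   ps$chrom[i + 1L], ps$start[i + 1L], ps$end[i + 1L]))
    }
  }
  seqs <- character(length(chrom_lengths))
  names(seqs) <- names(chrom_lengths)
  for (chrom in names(chrom_lengths)) {
    set.seed(derive_seed(seed, paste0("genome:", chrom)))
    chars <- strsplit(random_dna(chrom_lengths[[chrom]], gc), "")[[1]]
    pl <- planted[planted$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(pl))) {
      u <- if (pl$strand[i] == "-") revcomp(unit) else unit
      run <- strsplit(strrep(u, pl$repeat_count[i]), "")[[1]]
      chars[(pl$start[i] + 1L):pl$end[i]] <- run
      chars[pl$start[i]] <- breaker_base(u)          # base before the run
      chars[pl$end[i] + 1L] <- breaker_base(u)       # base after the run
    }
    seqs[[chrom]] <- paste(chars, collapse = "")
  }
  ## exhaustive oracle census at min_repeats = 1
  all_runs <- scan_genome(seqs, repeat_unit(unit, 1L), both_strands = TRUE)
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  planted_out <- planted[order(planted$chrom, planted$start),
                         c("chrom", "start", "end", "strand", "repeat_count")]
  rownames(planted_out) <- NULL
  accidental <- all_runs[!(key(all_runs) %in% key(planted_out)),
                         c("chrom", "start", "end", "strand", "score")]
  names(accidental)[names(accidental) == "score"] <- "repeat_count"
  rownames(accidental) <- NULL
  truth <- list(planted_runs = planted_out, accidental_runs = accidental,
                genome_length = as.list(chrom_lengths), gc_content = gc,
                unit = unit)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    write_fasta(seqs, fa)
    jsonlite::write_json(truth, file.path(out_dir, "genome_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(planted_out, file.path(out_dir, "planted_runs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- list(fasta = fa)
  }
  list(seqs = seqs, truth = truth, paths = paths)
}

#' Generate gene models, optionally pinning msats into contexts
#'
#' Random non-overlapping genes (one TSS per gene; first-exon start on
#' \code{+}, last-exon end on \code{-}) are laid down along each chromosome.
#' A layout can pin a microsatellite into a requested context class by
#' placing a dedicated gene around it:
#' \itemize{
#'   \item \code{promoter_proximal}: a gene whose TSS sits \code{interval}
#'     bp from the msat edge, inside the promoter window (error if
#'     \code{interval} exceeds the window's upstream reach);
#'   \item \code{exonic} / \code{intronic}: a gene spanning the msat with the
#'     msat inside an exon / between exons, at least 500 bp from the TSS;
#'   \item \code{intergenic}: an exclusion zone keeps all genes (and their
#'     promoter windows) away from the msat.
#' }
#'
#' @param n_genes number of additional random genes.
#' @param chrom_lengths named integer vector.
#' @param layout optional data.frame with \code{chrom}, \code{start},
#'   \code{end} (msat, 0-based half-open), \code{class}, optional
#'   \code{interval} (promoter gap, default 49) and \code{gene_strand}
#'   (default "+").
#' @param seed root seed.
#' @param window \code{\link{promoter_window}} the layout must honor.
#' @param out_dir if given, writes \code{genes.gff3} and a layout sidecar.
#' @return gene-model list (\code{genes}, \code{exons}) plus \code{layout}
#'   (with realized \code{gene_id}).
#' @export
make_annotation <- function(n_genes, chrom_lengths, layout = NULL, seed = 1L,
                            window = promoter_window(), out_dir = NULL) {
  set.seed(derive_seed(seed, "annotation"))
  genes <- list(); exons <- list(); gid <- 0L
  add_gene <- function(chrom, start, end, strand, exon_df) {
    gid <<- gid + 1L
    id <- sprintf("gene%04d", gid)
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, chrom = chrom, strand = strand,
      start = as.integer(start), end = as.integer(end),
      tss = as.integer(if (strand == "-") end - 1L else start),
      stringsAsFactors = FALSE)
    exon_df$gene_id <- id
    exons[[length(exons) + 1L]] <<- exon_df
    id
  }
  exclusion <- data.frame(chrom = character(), start = integer(), end = integer())
  reserve <- function(chrom, start, end) {
    exclusion <<- rbind(exclusion, data.frame(chrom = chrom,
                                              start = as.integer(start),
                                              end = as.integer(end)))
  }

  layout_out <- NULL
  if (!is.null(layout)) {
    stopifnot(all(c("chrom", "start", "end", "class") %in% names(layout)))
    layout$interval <- if ("interval" %in% names(layout)) layout$interval else 49L
    layout$gene_strand <- if ("gene_strand" %in% names(layout)) layout$gene_strand else "+"
    layout$gene_id <- NA_character_
    pad <- window$upstream + window$downstream + 1000L
    for (i in seq_len(nrow(layout))) {
      li <- layout[i, ]
      len <- chrom_lengths[[li$chrom]]
      if (li$class == "promoter_proximal") {
        if (li$interval > window$upstream) {
          stop("unsatisfiable layout: promoter placement at interval ",
               li$interval, " bp exceeds the ", window$upstream,
               " bp upstream window")
        }
        if (li$gene_strand == "+") {
          t0 <- li$end + li$interval
          gs <- t0; ge <- min(t0 + 1500L, len)
        } else {
          t0 <- li$start - li$interval - 1L
          gs <- max(t0 - 1499L, 0L); ge <- t0 + 1L
        }
        if (t0 < 0L || t0 >= len) stop("unsatisfiable layout: TSS off chromosome")
        ex <- data.frame(start = gs, end = ge)
        layout$gene_id[i] <- add_gene(li$chrom, gs, ge, li$gene_strand, ex)
        reserve(li$chrom, min(gs, li$start) - pad, max(ge, li$end) + pad)
      } else if (li$class %in% c("intronic", "exonic")) {
        gs <- li$start - 500L; ge <- li$end + 500L
        if (gs < 0L || ge > len) stop("unsatisfiable layout: flanks off chromosome")
        ex <- if (li$class == "intronic") {
          data.frame(start = c(gs, ge - 100L), end = c(gs + 100L, ge))
        } else {
          data.frame(start = gs, end = ge)
        }
        layout$gene_id[i] <- add_gene(li$chrom, gs, ge, li$gene_strand, ex)
        reserve(li$chrom, gs - pad, ge + pad)
      } else if (li$class == "intergenic") {
        reserve(li$chrom, li$start - pad, li$end + pad)
      } else {
        stop("unknown layout class: ", li$class)
      }
    }
    layout_out <- layout
  }

  ## random filler genes, walked left to right with random gaps, skipping
  ## exclusion zones
  placed <- 0L
  for (chrom in names(chrom_lengths)) {
    if (placed >= n_genes) break
    len <- chrom_lengths[[chrom]]
    zones <- exclusion[exclusion$chrom == chrom, , drop = FALSE]
    pos <- window$upstream + 100L   # keep the first promoter window on-chrom
    while (placed < n_genes && pos < len - 3000L) {
      pos <- pos + sample(300:1500, 1L)
      glen <- sample(500:2000, 1L)
      gs <- pos; ge <- pos + glen
      hit <- nrow(zones) > 0L &&
        any(gs - window$upstream - 100L < zones$end &
            ge + window$upstream + 100L > zones$start)
      if (hit) {
        ## jump fully past the blocking zone (plus the promoter margin)
        pos <- max(zones$end[zones$start < ge + window$upstream + 100L]) +
          window$upstream + 200L
        next
      }
      if (ge > len) break
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(1:4, 1L)
      ## exon boundaries: cut the span at sorted interior points
      cuts <- sort(sample(seq(gs + 50L, ge - 50L, by = 10L),
                          2L * (n_ex - 1L)))
      ex_start <- c(gs, cuts[seq_along(cuts) %% 2L == 0L])
      ex_end <- c(cuts[seq_along(cuts) %% 2L == 1L], ge)
      add_gene(chrom, gs, ge, strand,
               data.frame(start = as.integer(ex_start),
                          end = as.integer(ex_end)))
      placed <- placed + 1L
      pos <- ge
    }
  }
  if (placed < n_genes) {
    stop("could not place ", n_genes, " genes; chromosome too short or ",
         "exclusion zones too large")
  }
  genes_df <- do.call(rbind, genes)
  exons_df <- do.call(rbind, exons)[, c("gene_id", "start", "end")]
  rownames(genes_df) <- rownames(exons_df) <- NULL
  models <- list(genes = genes_df, exons = exons_df, layout = layout_out)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(models, file.path(out_dir, "genes.gff3"))
    if (!is.null(layout_out)) {
      write.table(layout_out, file.path(out_dir, "layout_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  models
}

#' Generate ChIP-style peaks covering a controlled fraction of runs
#'
#' Exactly \code{round(bound_fraction * n)} of the universe runs (truth runs
#' with \code{repeat_count >= min_repeats}) are overlapped by a peak; the
#' remaining runs overlap no peak. Peaks extend \code{margin} bp beyond the
#' run with uniform edge jitter of up to \code{jitter} bp (inward), clamped
#' so no peak reaches a neighboring universe run.
#'
#' @param genome output of \code{\link{make_genome}} (or its \code{truth}).
#' @param bound_fraction fraction of runs to cover, in [0, 1].
#' @param jitter maximal edge perturbation, bp; must not exceed
#'   \code{margin}.
#' @param margin peak extension beyond the run, bp.
#' @param min_repeats universe threshold (default 4, the binding threshold).
#' @param seed root seed.
#' @param out_dir if given, writes \code{peaks.bed} and
#'   \code{bound_truth.tsv}.
#' @return list with \code{peaks} (chrom/start/end BED-like data.frame) and
#'   \code{bound_truth}: the universe runs with a logical \code{bound}.
#' @export
make_peaks <- function(genome, bound_fraction, jitter = 0L, margin = 20L,
                       min_repeats = 4L, seed = 1L, out_dir = NULL) {
  stopifnot(bound_fraction >= 0, bound_fraction <= 1)
  if (jitter > margin) {
    stop("jitter (", jitter, ") larger than the guaranteed margin (",
         margin, ")")
  }
  truth <- if (!is.null(genome$truth)) genome$truth else genome
  runs <- rbind(truth$planted_runs, truth$accidental_runs)
  runs <- runs[runs$repeat_count >= min_repeats, , drop = FALSE]
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  n <- nrow(runs)
  n_bound <- round(bound_fraction * n)
  set.seed(derive_seed(seed, "peaks"))
  bound_idx <- sort(sample.int(n, n_bound))
  runs$bound <- seq_len(n) %in% bound_idx
  lens <- unlist(truth$genome_length)
  peaks <- NULL
  for (i in bound_idx) {
    chrom <- runs$chrom[i]
    same <- which(runs$chrom == chrom)
    prev_end <- if (any(same < i)) max(runs$end[same[same < i]]) else 0L
    next_start <- if (any(same > i)) min(runs$start[same[same > i]]) else lens[[chrom]]
    j1 <- if (jitter > 0L) sample(0:jitter, 1L) else 0L
    j2 <- if (jitter > 0L) sample(0:jitter, 1L) else 0L
    ps <- max(runs$start[i] - margin + j1, prev_end, 0L)
    pe <- min(runs$end[i] + margin - j2, next_start, lens[[chrom]])
    peaks <- rbind(peaks, data.frame(chrom = chrom, start = as.integer(ps),
                                     end = as.integer(pe),
                                     name = sprintf("peak%05d", i),
                                     score = 0L, strand = ".",
                                     stringsAsFactors = FALSE))
  }
  if (is.null(peaks)) peaks <- empty_hit_table()
  out <- list(peaks = peaks, bound_truth = runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(peaks, file.path(out_dir, "peaks.bed"))
    write.table(runs, file.path(out_dir, "bound_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Default normal-tissue composition: 70 tissue types, 928 samples
#'
#' Mirrors the published screen dimensions (50 tumors versus 928 normal
#' samples across 70 tissue types); sizes are spread as evenly as 928/70
#' allows (18 tissues of 14 samples, 52 of 13).
#' @export
default_tissue_sizes <- function() {
  sizes <- rep(13L, 70L)
  sizes[seq_len(928L - 13L * 70L)] <- 14L
  setNames(sizes, sprintf("tissue%02d", 1:70))
}

#' Generate a tumor-versus-normal expression matrix with planted effects
#'
#' Unplanted genes are drawn i.i.d. per sample around a common per-gene
#' baseline (uniform on [4, 12] log2 units); planted genes have their tumor
#' samples shifted upward by the per-gene effect size.
#'
#' @param n_genes total genes.
#' @param planted data.frame with \code{gene_id} (must exist among the
#'   generated ids \code{g0001}...) and \code{effect} (log2 shift, > 0);
#'   NULL for a null matrix.
#' @param n_tumor tumor sample count (default 50).
#' @param tissue_sizes named integer vector tissue -> sample count
#'   (default \code{\link{default_tissue_sizes}}); each must be >= 2.
#' @param noise_sd per-sample Gaussian noise, log2 units.
#' @param seed root seed.
#' @param out_dir if given, writes \code{expression.tsv},
#'   \code{labels.tsv} and \code{expression_truth.tsv}.
#' @return list with \code{matrix} (genes x samples), \code{labels} (named
#'   sample -> group), \code{truth} (planted table).
#' @export
make_expression <- function(n_genes = 500L, planted = NULL, n_tumor = 50L,
                            tissue_sizes = default_tissue_sizes(),
                            noise_sd = 0.5, seed = 1L, out_dir = NULL) {
  stopifnot(n_tumor >= 1L, all(tissue_sizes >= 2L), noise_sd >= 0)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  if (!is.null(planted)) {
    stopifnot(all(c("gene_id", "effect") %in% names(planted)),
              all(planted$effect > 0))
    if (anyDuplicated(planted$gene_id)) stop("duplicate gene ids in planted")
    if (!all(planted$gene_id %in% genes)) stop("planted gene_id not in matrix")
  }
  groups <- c(rep("tumor", n_tumor),
              rep(names(tissue_sizes), tissue_sizes))
  samples <- sprintf("s%04d", seq_along(groups))
  labels <- setNames(groups, samples)
  set.seed(derive_seed(seed, "expression"))
  baseline <- runif(n_genes, 4, 12)
  m <- matrix(rnorm(n_genes * length(samples), mean = baseline, sd = noise_sd),
              nrow = n_genes, ncol = length(samples),
              dimnames = list(genes, samples))
  if (!is.null(planted)) {
    idx <- match(planted$gene_id, genes)
    m[idx, groups == "tumor"] <- m[idx, groups == "tumor"] + planted$effect
  }
  out <- list(matrix = m, labels = labels,
              truth = planted %||% data.frame(gene_id = character(),
                                              effect = numeric()))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(gene_id = genes, m, check.names = FALSE),
                file.path(out_dir, "expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = samples, group = groups),
                file.path(out_dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$truth, file.path(out_dir, "expression_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate dose-response measurements from a 3PL model
#'
#' Response at dose x is \code{d / (1 + exp(b (ln x - ln e)))} plus Gaussian
#' noise with SD \code{noise_sd * d}; one row per dose and replicate, plus
#' vehicle rows (dose 0) at the upper asymptote that downstream fitting uses
#' only for normalization.
#'
#' @param d upper asymptote (response fraction).
#' @param b slope (> 0 means response falls with dose).
#' @param e ED50, micromolar, > 0.
#' @param doses positive doses, micromolar (sorted internally).
#' @param replicates per-dose replicate count, >= 1.
#' @param noise_sd Gaussian noise as a fraction of \code{d}.
#' @param vehicle include vehicle (dose 0) rows.
#' @param seed root seed.
#' @param out_dir if given, writes \code{dose_response.tsv} and a truth
#'   sidecar.
#' @return data.frame with \code{dose}, \code{replicate}, \code{response};
#'   truth attached as attribute \code{truth}.
#' @export
make_dose_response <- function(d = 1, b = 1, e = 0.4,
                               doses = 10^seq(-3, 2, length.out = 8),
                               replicates = 4L, noise_sd = 0.05,
                               vehicle = TRUE, seed = 1L, out_dir = NULL) {
  stopifnot(e > 0, replicates >= 1L, noise_sd >= 0)
  if (any(doses <= 0)) stop("doses must be strictly positive")
  doses <- sort(doses)
  set.seed(derive_seed(seed, "doseresponse"))
  grid <- expand.grid(replicate = seq_len(replicates), dose = doses)
  resp <- ll3(grid$dose, d, b, e) + rnorm(nrow(grid), 0, noise_sd * d)
  out <- data.frame(dose = grid$dose, replicate = grid$replicate,
                    response = resp)
  if (vehicle) {
    veh <- data.frame(dose = 0, replicate = seq_len(replicates),
                      response = d + rnorm(replicates, 0, noise_sd * d))
    out <- rbind(veh, out)
  }
  truth <- list(d = d, b = b, e = e, doses = doses, replicates = replicates,
                noise_sd = noise_sd)
  attr(out, "truth") <- truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(out_dir, "dose_response.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "dose_response_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
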