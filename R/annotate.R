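#' Microsatellite annotation against ChIP peaks and gene models
#'
#' A microsatellite becomes therapeutically interesting when it is actually
#' bound by the fusion oncoprotein (evidenced by a ChIP-seq peak) and when its
#' position relative to a transcriptional start site says something about the
#' genes it could drive. These functions flag peak overlap, classify genomic
#' context, and compute the msat-to-TSS interval, strand-aware.
#'
#' @name msat-annotation
NULL

#' Promoter-proximity window around a TSS
#'
#' The default window, -1000 bp to +100 bp around the TSS in gene
#' orientation, is the proximity definition used to single out
#' promoter-proximal fusion-bound microsatellites (such as the one 49 bp
#' upstream of the FEZF1-AS1 TSS).
#'
#' @param upstream bp upstream of the TSS (gene orientation), >= 0.
#' @param downstream bp downstream of the TSS, >= 0.
#' @export
promoter_window <- function(upstream = 1000L, downstream = 100L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream >= 0L, downstream >= 0L)
  structure(list(upstream = upstream, downstream = downstream),
            class = "promoter_window")
}

## shared seqlevel universe avoids spurious seqinfo-merge warnings when the
## two sides mention different chromosomes
hits_to_gr <- function(hits, universe = unique(hits$chrom)) {
  GenomicRanges::GRanges(factor(hits$chrom, levels = universe),
                         IRanges::IRanges(hits$start + 1L, hits$end))
}

#' Flag peak-bound microsatellites
#'
#' @param hits msat table (chrom, start, end, 0-based half-open), e.g. from
#'   \code{\link{scan_genome}}.
#' @param peaks peak table with chrom, start, end (0-based half-open).
#' @param min_overlap minimum overlap in bp to call a hit bound (default 1).
#' @return logical vector, one flag per row of \code{hits}. Half-open
#'   adjacency (peak end == msat start) is not an overlap.
#' @export
flag_bound <- function(hits, peaks, min_overlap = 1L) {
  if (nrow(hits) == 0L) return(logical(0))
  if (any(peaks$end <= peaks$start)) stop("peaks must satisfy start < end")
  missing_chroms <- setdiff(unique(hits$chrom), unique(peaks$chrom))
  if (length(missing_chroms) > 0L && nrow(peaks) > 0L) {
    warning("no peaks on chromosome(s): ", paste(missing_chroms, collapse = ", "))
  }
  if (nrow(peaks) == 0L) return(rep(FALSE, nrow(hits)))
  uni <- union(hits$chrom, peaks$chrom)
  ov <- GenomicRanges::countOverlaps(hits_to_gr(hits, uni),
                                     hits_to_gr(peaks, uni),
                                     minoverlap = as.integer(min_overlap))
  ov > 0L
}

#' Annotate microsatellites with binding, context and TSS interval
#'
#' Classifies each msat into exactly one genomic context with precedence
#' promoter_proximal > exonic > intronic > intergenic:
#' \itemize{
#'   \item \code{promoter_proximal}: any part of the msat lies within the
#'     promoter window of some gene, in gene orientation (for a minus-strand
#'     gene with TSS t the window in genome coordinates is
#'     \code{[t - downstream, t + upstream]});
#'   \item \code{exonic}: overlaps an exon;
#'   \item \code{intronic}: inside a gene span but no exon;
#'   \item \code{intergenic}: otherwise.
#' }
#' \code{interval_bp} is the number of bases strictly between the msat edge
#' nearest the TSS and the nearest TSS on the same chromosome (0 when the
#' msat overlaps or abuts the TSS); \code{signed_tss_offset} carries the same
#' magnitude with sign negative when the msat lies upstream of that TSS in
#' gene orientation. Ties on distance resolve to the smallest gene_id.
#'
#' @param hits msat table (chrom, start, end; 0-based half-open).
#' @param genes gene-model list (\code{\link{read_gene_models}} format).
#' @param peaks optional peak table; when supplied, a \code{bound} column is
#'   added via \code{\link{flag_bound}}.
#' @param window a \code{\link{promoter_window}}.
#' @param min_overlap passed to \code{\link{flag_bound}}.
#' @return \code{hits} with added columns \code{bound} (if peaks given),
#'   \code{context}, \code{interval_bp}, \code{signed_tss_offset},
#'   \code{nearest_gene}.
#' @export
annotate_msats <- function(hits, genes, peaks = NULL,
                           window = promoter_window(), min_overlap = 1L) {
  stopifnot(inherits(window, "promoter_window"))
  out <- hits
  if (!is.null(peaks)) out$bound <- flag_bound(hits, peaks, min_overlap)
  n <- nrow(hits)
  out$context <- rep("intergenic", n)
  out$interval_bp <- rep(NA_integer_, n)
  out$signed_tss_offset <- rep(NA_integer_, n)
  out$nearest_gene <- rep(NA_character_, n)
  if (n == 0L) return(out)
  g <- genes$genes
  if (is.null(g) || nrow(g) == 0L) return(out)

  uni <- union(unique(hits$chrom), unique(g$chrom))
  hit_gr <- hits_to_gr(hits, uni)

  ## nearest TSS (per chromosome, unlimited distance), tie -> smallest gene_id
  tss_gr <- GenomicRanges::GRanges(factor(g$chrom, levels = uni),
                                   IRanges::IRanges(g$tss + 1L, g$tss + 1L))
  dtn <- GenomicRanges::distanceToNearest(hit_gr, tss_gr, select = "all")
  if (length(dtn) > 0L) {
    qh <- S4Vectors::queryHits(dtn); sh <- S4Vectors::subjectHits(dtn)
    d <- S4Vectors::mcols(dtn)$distance
    ord <- order(qh, d, g$gene_id[sh])
    first <- ord[!duplicated(qh[ord])]
    out$interval_bp[qh[first]] <- as.integer(d[first])
    out$nearest_gene[qh[first]] <- g$gene_id[sh[first]]
    ## sign: upstream in gene orientation is negative
    gi <- sh[first]; hi <- qh[first]
    t0 <- g$tss[gi]; str <- g$strand[gi]
    before <- hits$end[hi] <= t0      # msat entirely left of the TSS base
    after <- hits$start[hi] > t0      # msat entirely right of the TSS base
    sgn <- integer(length(hi))        # overlap -> 0
    sgn[before] <- ifelse(str[before] == "+", -1L, 1L)
    sgn[after] <- ifelse(str[after] == "+", 1L, -1L)
    out$signed_tss_offset[hi] <- sgn * as.integer(d[first])
  }

  ## promoter windows, strand-aware, clamped at chromosome origin
  up <- window$upstream; down <- window$downstream
  wstart0 <- ifelse(g$strand == "-", g$tss - down, g$tss - up)
  wend0 <- ifelse(g$strand == "-", g$tss + up, g$tss + down)
  win_gr <- GenomicRanges::GRanges(
    factor(g$chrom, levels = uni),
    IRanges::IRanges(pmax(wstart0, 0L) + 1L, wend0 + 1L))
  in_prom <- GenomicRanges::countOverlaps(hit_gr, win_gr) > 0L

  ## exon / gene-span overlap
  e <- genes$exons
  in_exon <- if (!is.null(e) && nrow(e) > 0L) {
    chrom_of <- setNames(g$chrom, g$gene_id)
    exon_gr <- GenomicRanges::GRanges(factor(chrom_of[e$gene_id], levels = uni),
                                      IRanges::IRanges(e$start + 1L, e$end))
    GenomicRanges::countOverlaps(hit_gr, exon_gr) > 0L
  } else rep(FALSE, n)
  span_gr <- GenomicRanges::GRanges(factor(g$chrom, levels = uni),
                                    IRanges::IRanges(g$start + 1L, g$end))
  in_span <- GenomicRanges::countOverlaps(hit_gr, span_gr) > 0L

  out$context[in_span] <- "intronic"
  out$context[in_exon] <- "exonic"
  out$context[in_prom] <- "promoter_proximal"
  out
}

#' Summarize an annotated msat census
#'
#' Context fractions are computed over \emph{bound} msats only, mirroring the
#' fusion-bound census (e.g. the observation that the vast majority of bound
#' GGAA-msats are intronic or intergenic while only a small fraction sit
#' within -1000/+100 bp of a RefSeq TSS).
#'
#' @param annotated output of \code{\link{annotate_msats}}; must contain a
#'   \code{bound} column (all-TRUE is supplied if absent).
#' @return list with \code{n_total}, \code{n_bound}, \code{fraction_by_context}
#'   (named numeric over bound msats; NA-flagged when \code{n_bound} is 0),
#'   \code{n_promoter_proximal}, \code{min_interval_bp} and
#'   \code{min_interval_gene} (over bound promoter-proximal msats; ties on
#'   interval resolve to the smallest gene_id).
#' @export
summarize_census <- function(annotated) {
  contexts <- c("promoter_proximal", "exonic", "intronic", "intergenic")
  if (is.null(annotated$bound)) annotated$bound <- rep(TRUE, nrow(annotated))
  b <- annotated[annotated$bound, , drop = FALSE]
  n_bound <- nrow(b)
  frac <- setNames(rep(NA_real_, length(contexts)), contexts)
  if (n_bound > 0L) {
    tab <- table(factor(b$context, levels = contexts))
    frac <- as.numeric(tab) / n_bound
    names(frac) <- contexts
  }
  prom <- b[b$context == "promoter_proximal", , drop = FALSE]
  min_iv <- NA_integer_; min_gene <- NA_character_
  if (nrow(prom) > 0L) {
    ord <- order(prom$interval_bp, prom$nearest_gene)
    min_iv <- prom$interval_bp[ord[1L]]
    min_gene <- prom$nearest_gene[ord[1L]]
  }
  list(n_total = nrow(annotated), n_bound = n_bound,
       fraction_by_context = frac,
       n_promoter_proximal = nrow(prom),
       min_interval_bp = min_iv, min_interval_gene = min_gene)
}
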