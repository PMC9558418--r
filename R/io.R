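#' File input/output
#'
#' Thin wrappers around Biostrings and rtracklayer that pin down the
#' package-wide coordinate convention: 0-based half-open everywhere in memory
#' and in BED output; GFF3 (1-based closed) is converted on the way in and out.
#'
#' @name neoenhancer-io
NULL

#' Write a hit/peak table as BED6
#'
#' @param x data.frame with chrom, start, end and optionally name, score,
#'   strand (0-based half-open).
#' @param path output path.
#' @param sorted sort by (chrom, start) before writing.
#' @export
write_bed <- function(x, path, sorted = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bed <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0L,
                    strand = if ("strand" %in% names(x)) x$strand else ".")
  if (sorted) bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a 0-based half-open data.frame
#'
#' @param path BED3-BED6 file.
#' @return data.frame chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else ".",
                   score = if (!is.null(gr$score)) gr$score else 0L,
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  df
}

#' Write gene models as GFF3
#'
#' Emits one \code{gene} record per gene and one \code{exon} record per exon
#' (with \code{Parent}), 1-based closed per the GFF3 specification.
#'
#' @param genes gene-model list as returned by \code{\link{read_gene_models}}
#'   or \code{\link{make_annotation}}: data.frame \code{genes}
#'   (gene_id, chrom, strand, start, end, tss) and data.frame \code{exons}
#'   (gene_id, start, end), all 0-based half-open.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  g <- genes$genes; e <- genes$exons
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id)
  chrom_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)
  exon_gr <- GenomicRanges::GRanges(
    chrom_of[e$gene_id], IRanges::IRanges(e$start + 1L, e$end),
    strand = strand_of[e$gene_id],
    type = "exon", ID = paste0(e$gene_id, ".e", seq_len(nrow(e))),
    Parent = e$gene_id)
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects \code{gene} records with an \code{ID} and \code{exon} records with
#' a \code{Parent}; one TSS per gene (multi-TSS genes must be pre-flattened).
#' The TSS is the 5' end of the gene span in gene orientation: span start on
#' \code{+}, last base of the span on \code{-}.
#'
#' @param path GFF3 file.
#' @return list with data.frames \code{genes} (gene_id, chrom, strand, start,
#'   end, tss; 0-based half-open, tss a 0-based position) and \code{exons}
#'   (gene_id, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- tolower(as.character(gr$type)) == "gene"
  is_exon <- tolower(as.character(gr$type)) == "exon"
  g <- gr[is_gene]
  strand <- as.character(GenomicRanges::strand(g))
  start0 <- GenomicRanges::start(g) - 1L
  end0 <- GenomicRanges::end(g)
  genes <- data.frame(gene_id = as.character(g$ID),
                      chrom = as.character(GenomicRanges::seqnames(g)),
                      strand = strand, start = start0, end = end0,
                      tss = ifelse(strand == "-", end0 - 1L, start0),
                      stringsAsFactors = FALSE)
  ex <- gr[is_exon]
  parent <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
  exons <- data.frame(gene_id = parent,
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write a named list of sequences as FASTA
#' @param seqs named character vector or DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read an expression matrix and its sample labels
#'
#' @param matrix_path TSV: first column gene ids, remaining columns samples,
#'   log2 intensities.
#' @param labels_path TSV with columns \code{sample} and \code{group}.
#' @return list(matrix = numeric matrix genes x samples, labels = named
#'   character vector sample -> group).
#' @export
read_expression <- function(matrix_path, labels_path) {
  m <- read.table(matrix_path, header = TRUE, sep = "\t", check.names = FALSE,
                  row.names = 1)
  lab <- read.table(labels_path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group") %in% names(lab)))
  labels <- setNames(lab$group, lab$sample)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  list(matrix = m, labels = labels[colnames(m)])
}

#' Read dose-response measurements
#'
#' @param path TSV with columns \code{dose} (micromolar; 0 = vehicle),
#'   \code{response} (fraction of vehicle control) and optionally
#'   \code{replicate} and grouping columns.
#' @return data.frame.
#' @export
read_dose_response <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("dose", "response") %in% names(d)))
  d
}
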