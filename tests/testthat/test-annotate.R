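make_models <- function(genes, exons) {
  # tiny hand-built gene-model list (0-based half-open, tss = 5' base)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  list(genes = genes, exons = exons)
}

test_that("flag_bound honors half-open overlap semantics", {
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  hits <- data.frame(chrom = "chr1",
                     start = c(150L, 200L, 84L, 0L),
                     end = c(170L, 216L, 100L, 50L))
  expect_equal(flag_bound(hits, peaks), c(TRUE, FALSE, FALSE, FALSE))
  # min_overlap raises the bar
  hits2 <- data.frame(chrom = "chr1", start = 195L, end = 210L)
  expect_true(flag_bound(hits2, peaks))
  expect_false(flag_bound(hits2, peaks, min_overlap = 6L))
  # chrom absent from peak universe warns, does not error
  hits3 <- data.frame(chrom = "chr9", start = 1L, end = 10L)
  expect_warning(fl <- flag_bound(hits3, peaks), "chr9")
  expect_false(fl)
})

test_that("flag_bound agrees with the quadratic all-pairs oracle", {
  set.seed(31)
  for (i in 1:30) {
    hits <- data.frame(chrom = sample(c("c1", "c2"), 25, replace = TRUE),
                       start = sample(0:980, 25))
    hits$end <- hits$start + sample(4:40, 25, replace = TRUE)
    peaks <- data.frame(chrom = sample(c("c1", "c2"), 10, replace = TRUE),
                        start = sample(0:950, 10))
    peaks$end <- peaks$start + sample(10:80, 10, replace = TRUE)
    for (mo in c(1L, 5L)) {
      expect_identical(
        suppressWarnings(flag_bound(hits, peaks, mo)),
        oracle_flag_bound(hits, peaks, mo))
    }
  }
})

test_that("promoter window is strand-aware and bounded", {
  models <- make_models(
    data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
               strand = c("+", "-"),
               start = c(10000L, 30000L), end = c(12000L, 32000L)),
    data.frame(gene_id = c("gA", "gB"),
               start = c(10000L, 30000L), end = c(12000L, 32000L)))
  w <- promoter_window(1000L, 100L)
  # + gene, TSS 10000: msat ending 49 bp upstream is promoter-proximal
  a <- annotate_msats(data.frame(chrom = "chr1", start = 9900L, end = 9951L),
                      models, window = w)
  expect_equal(a$context, "promoter_proximal")
  expect_equal(a$interval_bp, 49L)
  expect_equal(a$signed_tss_offset, -49L)
  # nearest edge 1001 bp upstream: outside the window
  a <- annotate_msats(data.frame(chrom = "chr1", start = 8900L, end = 8999L),
                      models, window = w)
  expect_equal(a$context, "intergenic")
  expect_equal(a$interval_bp, 1001L)
  # - gene, TSS 31999: genomic window is [tss - downstream, tss + upstream]
  a <- annotate_msats(data.frame(chrom = "chr1", start = 32500L, end = 32516L),
                      models, window = w)
  expect_equal(a$context, "promoter_proximal")
  expect_equal(a$signed_tss_offset, -500L)      # upstream in gene orientation
  a <- annotate_msats(data.frame(chrom = "chr1", start = 31900L, end = 31916L),
                      models, window = w)
  expect_equal(a$context, "promoter_proximal")  # within +100 downstream
  a <- annotate_msats(data.frame(chrom = "chr1", start = 31700L, end = 31796L),
                      models, window = w)
  expect_equal(a$context, "exonic")             # past downstream edge, in exon
  expect_equal(a$signed_tss_offset, 203L)
})

test_that("context precedence and intronic classification on a minus-strand gene", {
  models <- make_models(
    data.frame(gene_id = "gM", chrom = "chr1", strand = "-",
               start = 5000L, end = 9000L),
    data.frame(gene_id = c("gM", "gM"),
               start = c(5000L, 8800L), end = c(5200L, 9000L)))
  # msat in the intron, far from the (right-end) TSS
  a <- annotate_msats(data.frame(chrom = "chr1", start = 6000L, end = 6100L),
                      models)
  expect_equal(a$context, "intronic")
  expect_equal(a$nearest_gene, "gM")
  # downstream in gene orientation => positive signed offset
  expect_gt(a$signed_tss_offset, 0)
  expect_equal(a$interval_bp, 2899L)  # gap to the tss base at 8999
  # exon overlap wins over intron
  a <- annotate_msats(data.frame(chrom = "chr1", start = 5150L, end = 5250L),
                      models)
  expect_equal(a$context, "exonic")
  # no genes on chromosome -> intergenic with NA gene
  a <- annotate_msats(data.frame(chrom = "chrX", start = 10L, end = 30L), models)
  expect_equal(a$context, "intergenic")
  expect_true(is.na(a$nearest_gene))
})

test_that("interval_bp is invariant under reverse-complementing the locus", {
  L <- 20000L
  models <- make_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 10000L, end = 12000L),
    data.frame(gene_id = "g1", start = 10000L, end = 12000L))
  hit <- data.frame(chrom = "chr1", start = 9700L, end = 9800L)
  a1 <- annotate_msats(hit, models)
  # mirror everything: positions p -> L - p, strand flips
  mirrored_models <- make_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
               start = L - 12000L, end = L - 10000L),
    data.frame(gene_id = "g1", start = L - 12000L, end = L - 10000L))
  a2 <- annotate_msats(data.frame(chrom = "chr1", start = L - 9800L,
                                  end = L - 9700L), mirrored_models)
  expect_equal(a1$interval_bp, a2$interval_bp)
  expect_equal(a1$context, a2$context)
  expect_equal(a1$signed_tss_offset, a2$signed_tss_offset)
})

test_that("every msat gets exactly one context and fractions sum to 1", {
  set.seed(77)
  models <- make_annotation(30, c(chr1 = 200000L), seed = 5)
  hits <- data.frame(chrom = "chr1", start = sample(0:199900, 200))
  hits$end <- hits$start + 16L
  a <- annotate_msats(hits, models)
  expect_true(all(a$context %in%
                  c("promoter_proximal", "exonic", "intronic", "intergenic")))
  s <- summarize_census(a)   # no bound column -> all treated as bound
  expect_equal(sum(s$fraction_by_context), 1)
  expect_equal(s$n_bound, 200L)
})

test_that("census summary: ties, zero-bound edge, promoter counting", {
  ann <- data.frame(
    chrom = "chr1", start = 1:4 * 100L, end = 1:4 * 100L + 16L,
    bound = c(TRUE, TRUE, TRUE, FALSE),
    context = c("promoter_proximal", "promoter_proximal", "intronic",
                "intergenic"),
    interval_bp = c(49L, 49L, 500L, 20L),
    nearest_gene = c("gB", "gA", "gC", "gD"))
  s <- summarize_census(ann)
  expect_equal(s$n_bound, 3L)
  expect_equal(s$n_promoter_proximal, 2L)
  expect_equal(s$min_interval_bp, 49L)
  expect_equal(s$min_interval_gene, "gA")   # tie broken by smallest gene_id
  expect_equal(unname(s$fraction_by_context["promoter_proximal"]), 2 / 3)
  # all msats promoter-proximal
  ann2 <- ann; ann2$context <- "promoter_proximal"; ann2$bound <- TRUE
  expect_equal(unname(summarize_census(ann2)$fraction_by_context[1]), 1)
  # zero bound msats: NA-flagged fractions
  ann$bound <- FALSE
  s0 <- summarize_census(ann)
  expect_equal(s0$n_bound, 0L)
  expect_true(all(is.na(s0$fraction_by_context)))
})
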