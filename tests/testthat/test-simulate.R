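test_that("planted runs are written verbatim and truth matches the oracle scan", {
  planted <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                        repeat_count = c(25L, 6L), strand = c("+", "-"))
  g <- make_genome(c(chr1 = 20000L), planted, seed = 7L)
  s <- g$seqs[["chr1"]]
  # verbatim placement, 0-based [1000, 1100) = GGAA x 25
  expect_identical(substring(s, 1001L, 1100L), strrep("GGAA", 25L))
  expect_identical(substring(s, 5001L, 5024L), strrep("TTCC", 6L))
  # exhaustive regex census (both strands) equals planted + accidental truth
  all_truth <- rbind(g$truth$planted_runs, g$truth$accidental_runs)
  all_truth <- all_truth[order(all_truth$start, all_truth$strand), ]
  fwd <- oracle_scan_regex(s, "GGAA", 1L)
  rev <- oracle_scan_regex(s, "TTCC", 1L)
  oracle <- rbind(data.frame(fwd, strand = "+"), data.frame(rev, strand = "-"))
  oracle <- oracle[order(oracle$start, oracle$strand), ]
  expect_equal(all_truth$start, oracle$start)
  expect_equal(all_truth$end, oracle$end)
  expect_equal(all_truth$strand, oracle$strand)
  expect_equal(all_truth$repeat_count, oracle$repeat_count)
  # planted and accidental are disjoint intervals
  key <- paste(all_truth$start, all_truth$strand)
  expect_false(anyDuplicated(key) > 0)
})

test_that("identical seed and config give byte-identical FASTA", {
  planted <- data.frame(chrom = "chr1", start = 500L, repeat_count = 8L,
                        strand = "+")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_genome(c(chr1 = 5000L), planted, seed = 7L, out_dir = d1)
  make_genome(c(chr1 = 5000L), planted, seed = 7L, out_dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                   unname(tools::md5sum(file.path(d2, "genome.fa"))))
  # different seed changes the background
  d3 <- withr::local_tempdir()
  make_genome(c(chr1 = 5000L), planted, seed = 8L, out_dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("overlapping or out-of-bounds planted runs are rejected", {
  bad <- data.frame(chrom = "chr1", start = c(100L, 110L),
                    repeat_count = c(10L, 4L), strand = "+")
  expect_error(make_genome(c(chr1 = 5000L), bad, seed = 1L),
               "overlapping planted runs.*\\[100,140\\).*\\[110,126\\)")
  oob <- data.frame(chrom = "chr1", start = 4990L, repeat_count = 5L,
                    strand = "+")
  expect_error(make_genome(c(chr1 = 5000L), oob, seed = 1L), "out of bounds")
})

test_that("scan_genome on a generated genome equals the recorded truth", {
  set.seed(99)
  starts <- seq(1000L, 90000L, by = 3000L)
  planted <- data.frame(chrom = "chr1", start = starts,
                        repeat_count = sample(4:25, length(starts), TRUE),
                        strand = sample(c("+", "-"), length(starts), TRUE))
  g <- make_genome(c(chr1 = 100000L), planted, seed = 12L)
  hits <- scan_genome(g$seqs, repeat_unit("GGAA", 1L))
  truth <- rbind(g$truth$planted_runs, g$truth$accidental_runs)
  truth <- truth[order(truth$start, truth$strand), ]
  expect_equal(nrow(hits), nrow(truth))
  expect_equal(hits$start, truth$start)
  expect_equal(hits$end, truth$end)
  expect_equal(hits$strand, truth$strand)
})

test_that("annotation layout pins contexts; GFF3 round-trips", {
  layout <- data.frame(chrom = "chr1",
                       start = c(10000L, 30000L), end = c(10100L, 30100L),
                       class = c("promoter_proximal", "intronic"),
                       interval = c(49L, NA), gene_strand = c("+", "+"))
  models <- make_annotation(20L, c(chr1 = 150000L), layout, seed = 4L)
  a <- annotate_msats(data.frame(chrom = "chr1", start = layout$start,
                                 end = layout$end), models)
  expect_equal(a$context, c("promoter_proximal", "intronic"))
  expect_equal(a$interval_bp[1], 49L)
  # minus-strand TSS convention: 5' base = last base of the span
  minus <- models$genes[models$genes$strand == "-", ]
  if (nrow(minus)) expect_equal(minus$tss, minus$end - 1L)
  # round trip through GFF3
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(models, path)
  rt <- read_gene_models(path)
  o1 <- models$genes[order(models$genes$gene_id), ]
  o2 <- rt$genes[order(rt$genes$gene_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  e1 <- models$exons[order(models$exons$gene_id, models$exons$start), ]
  e2 <- rt$exons[order(rt$exons$gene_id, rt$exons$start), ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1, e2)
})

test_that("unsatisfiable layouts are rejected with the constraint named", {
  layout <- data.frame(chrom = "chr1", start = 10000L, end = 10100L,
                       class = "promoter_proximal", interval = 2000L)
  expect_error(make_annotation(5L, c(chr1 = 50000L), layout, seed = 1L),
               "unsatisfiable layout.*upstream window")
})

test_that("peaks cover exactly the requested fraction of runs", {
  set.seed(5)
  starts <- seq(1000L, 40 * 2400L, by = 2400L)   # 40 well-separated runs
  planted <- data.frame(chrom = "chr1", start = starts,
                        repeat_count = sample(4:20, 40, TRUE),
                        strand = "+")
  g <- make_genome(c(chr1 = 110000L), planted, seed = 2L)
  # keep the universe to the planted runs (accidental runs are all < 4)
  for (bf in c(0, 0.5, 1)) {
    pk <- make_peaks(g, bf, jitter = 5L, margin = 20L, seed = 9L)
    hits <- scan_genome(g$seqs, repeat_unit("GGAA", 4L))
    fl <- suppressWarnings(flag_bound(hits, pk$peaks))
    expect_equal(sum(fl), round(bf * nrow(hits)))
    # flags equal the recorded truth exactly
    expect_equal(fl, pk$bound_truth$bound[match(paste(hits$chrom, hits$start),
                                                paste(pk$bound_truth$chrom,
                                                      pk$bound_truth$start))])
  }
  expect_error(make_peaks(g, 0.5, jitter = 30L, margin = 20L),
               "jitter.*larger than")
})

test_that("expression generator: dimensions, planting, validation", {
  ex <- make_expression(n_genes = 40L,
                        planted = data.frame(gene_id = "g0003", effect = 4),
                        noise_sd = 0.5, seed = 3L)
  # default world: 50 tumors + 928 normals over 70 tissue types
  expect_equal(dim(ex$matrix), c(40L, 978L))
  expect_equal(sum(ex$labels == "tumor"), 50L)
  expect_equal(length(unique(ex$labels[ex$labels != "tumor"])), 70L)
  expect_equal(sum(default_tissue_sizes()), 928L)
  # planted construction: tumor mean is ~effect above every tissue mean
  tum <- rowMeans(ex$matrix[, ex$labels == "tumor"])
  tis_means <- vapply(unique(ex$labels[ex$labels != "tumor"]), function(t)
    mean(ex$matrix["g0003", ex$labels == t]), numeric(1))
  expect_true(all(tum["g0003"] - tis_means > 3))
  expect_error(
    make_expression(planted = data.frame(gene_id = c("g0001", "g0001"),
                                         effect = c(1, 2))),
    "duplicate")
  expect_error(make_expression(planted = data.frame(gene_id = "nope",
                                                    effect = 1)),
               "not in matrix")
})

test_that("dose-response generator honors the 3PL model", {
  # noiseless: midpoint identity and asymptote behavior
  dr <- make_dose_response(d = 0.8, b = 2, e = 1,
                           doses = c(1e-4, 0.01, 1, 100, 1e4),
                           replicates = 1L, noise_sd = 0, seed = 1L)
  resp <- dr$response[dr$dose > 0]
  expect_equal(resp[dr$dose[dr$dose > 0] == 1], 0.4)         # d/2 at x = e
  expect_lt(abs(resp[1] - 0.8), 1e-6)                        # x -> 0: d
  expect_lt(resp[length(resp)], 1e-6)                        # x -> inf: 0
  # vehicle rows present at the upper asymptote
  expect_equal(sum(dr$dose == 0), 1L)
  expect_equal(dr$response[dr$dose == 0], 0.8)
  expect_error(make_dose_response(doses = c(0.1, -1)), "strictly positive")
  expect_error(make_dose_response(e = -1), "e > 0")
  # determinism
  a <- make_dose_response(seed = 5L); b <- make_dose_response(seed = 5L)
  expect_identical(a, b)
})
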