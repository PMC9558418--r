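test_that("GGAA cassettes round-trip their repeat counts through the scanner", {
  for (n in c(17L, 21L, 25L)) {
    d <- design_ggaa_cassette(n)
    h <- scan_sequence(d$assembled)
    expect_equal(nrow(h), 1L)
    expect_equal(h$repeat_count, n)
    expect_equal(h$end - h$start, 4L * n)
    # enhancer feature sits at the very start ("directly upstream")
    expect_equal(d$features$role[1], "enhancer")
    expect_equal(d$features$start[1], 0L)
    expect_equal(d$features$role[2], "min_promoter")
  }
  # the 25-repeat knock-in block is 100 bp
  d25 <- design_ggaa_cassette(25L)
  expect_equal(scan_sequence(d25$assembled)$end, 100L)
})

test_that("repeat-free control cassette re-scans to zero hits", {
  d0 <- design_ggaa_cassette(0L)
  expect_equal(nrow(scan_sequence(d0$assembled)), 0L)
  expect_false("enhancer" %in% d0$features$role)
})

test_that("assembly is deterministic", {
  d1 <- design_ggaa_cassette(21L)
  d2 <- design_ggaa_cassette(21L)
  expect_identical(d1$assembled, d2$assembled)
  expect_identical(d1$features, d2$features)
})

test_that("junction guard catches promoter edges that extend the run", {
  # adversarial promoter starting with GGAA would extend a 4-repeat block
  evil <- cassette_part("evil_promoter", "min_promoter", "GGAATATATAATGCC")
  expect_error(design_ggaa_cassette(4L, min_promoter = evil,
                                    auto_spacer = FALSE),
               "junction guard")
  # auto spacer rescues the design with a 1-bp neutral insertion
  d <- design_ggaa_cassette(4L, min_promoter = evil, auto_spacer = TRUE)
  h <- scan_sequence(d$assembled)
  expect_equal(h$repeat_count, 4L)
  expect_true("junction_spacer" %in% d$features$name)
})

test_that("payload preconditions are enforced", {
  bad <- list(cassette_part("noatg", "orf", "CCCTTTAAA"))
  expect_error(design_ggaa_cassette(25L, payloads = bad), "ATG")
  bad_linker <- cassette_part("L", "linker", "GGCC")
  expect_error(design_ggaa_cassette(25L, linker = bad_linker), "divisible by 3")
})

test_that("p3f1 cassette: repair and motif multimerization", {
  base <- synthetic_alk_base()
  expect_equal(count_exact_matches(base), 0L)
  d_syn <- design_p3f1_cassette(base, repair = TRUE, extra_motifs = 0L)
  expect_equal(count_exact_matches(d_syn$assembled), 1L)
  d3 <- design_p3f1_cassette(base, repair = TRUE, extra_motifs = 3L)
  d5 <- design_p3f1_cassette(base, repair = TRUE, extra_motifs = 5L)
  expect_equal(count_exact_matches(d3$assembled) -
               count_exact_matches(d_syn$assembled), 3L)
  expect_equal(count_exact_matches(d5$assembled) -
               count_exact_matches(d_syn$assembled), 5L)
  # no repair, no extras: motif dose stays zero
  d_raw <- design_p3f1_cassette(base, repair = FALSE, extra_motifs = 0L)
  expect_equal(count_exact_matches(d_raw$assembled), 0L)
  # no GGAA run may be created by assembly
  expect_equal(nrow(scan_sequence(d5$assembled)), 0L)
})

test_that("p3f1 repair errors when no near-match exists", {
  set.seed(3)
  base <- paste(rep("C", 300), collapse = "")
  expect_error(design_p3f1_cassette(base, repair = TRUE), "no match")
})

test_that("validate_design: frame integrity across P2A linkers", {
  d <- design_ggaa_cassette(25L)     # [TK-stub][P2A][Luc-stub] bicistron
  rep <- validate_design(d)
  expect_true(rep$frame_check$ok)
  expect_true(rep$tiling_ok)
  expect_true(rep$pass)
  expect_equal(rep$msat_max_repeats, 25L)

  # cytokine-style bicistron stand-ins pass too
  il15 <- cassette_part("IL15_stub_synthetic", "orf",
                        "ATGAACTGGGTTAACGTCATCAGC")
  xcl1 <- cassette_part("XCL1_stub_synthetic", "orf",
                        "ATGAGACTTCTCCTCCTGACTTAA")
  d_ix <- design_ggaa_cassette(25L, payloads = list(il15, xcl1))
  expect_true(validate_design(d_ix)$frame_check$ok)

  # a 1-bp shift in ORF2 breaks the frame and is localized
  shifted <- cassette_part("Fluc_shift", "orf",
                           "ATGATTCCTGAGCGTTCACTGTCGATTGAACTAA")
  d_bad <- design_ggaa_cassette(25L,
                                payloads = list(default_payloads()[[1]],
                                                shifted))
  rep_bad <- validate_design(d_bad)
  expect_false(rep_bad$frame_check$ok)
  expect_false(rep_bad$pass)
})

test_that("enhancer scoring reflects the binding-length preference", {
  expect_true(score_enhancer(25)$in_optimal_band)     # band edge
  expect_true(score_enhancer(15)$in_optimal_band)
  expect_false(score_enhancer(26)$in_optimal_band)
  expect_false(score_enhancer(14)$in_optimal_band)
  s4 <- score_enhancer(4)
  expect_true(s4$meets_threshold)                     # bound, but not optimal
  expect_false(s4$in_optimal_band)
  expect_false(score_enhancer(3)$meets_threshold)
})

test_that("default parts carry no hidden motifs or runs", {
  for (p in c(list(yb_tata_promoter(), kozak_part()), default_payloads())) {
    expect_equal(nrow(scan_sequence(p$sequence, repeat_unit("GGAA", 2L))), 0L)
    expect_equal(count_exact_matches(p$sequence), 0L)
  }
  # P2A holds a single GGAA copy (from its glycine-serine codons), no run
  expect_equal(nrow(scan_sequence(p2a_linker()$sequence)), 0L)
})

test_that("GenBank-style output round-trips the feature table", {
  d <- design_ggaa_cassette(17L)
  path <- withr::local_tempfile(fileext = ".gb")
  write_cassette_genbank(d, path, name = "ggaa17")
  txt <- readLines(path)
  expect_true(any(grepl("^LOCUS", txt)))
  expect_equal(sum(grepl("misc_feature", txt)), nrow(d$features))
  expect_true(any(grepl("GGAAx17", txt)))
  # sequence lines reconstruct the assembly
  ori <- txt[(which(txt == "ORIGIN") + 1):(length(txt) - 1)]
  seq <- toupper(gsub("[^a-z]", "", paste(ori, collapse = "")))
  expect_identical(seq, d$assembled)
})
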