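Package: neoenhancer
Title: Design and Analysis of Fusion-Oncoprotein Neo-Enhancer Expression Cassettes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for exploiting the neomorphic DNA binding of sarcoma fusion
    transcription factors (EWSR1-FLI1 GGAA microsatellites, PAX3-FOXO1
    ATTWGTCACGGT motifs) for tumor-specific transgene expression: a maximal
    tandem-repeat scanner, ChIP-peak and TSS annotation of microsatellites,
    IUPAC consensus motif matching and minimal-edit repair, synthetic
    enhancer/minimal-promoter cassette assembly with junction guards, a
    tumor-versus-all-normal-tissues overexpression screen with surface-protein
    filtering, and three-parameter log-logistic dose-response (ED50) fitting
    with bootstrap confidence intervals. A seeded synthetic-data module
    generates every input format with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
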