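---
title: "Methods: models, conventions and design choices in neoenhancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in neoenhancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoenhancer)
```

## The biological problem

Ewing sarcoma is driven by the EWSR1-FLI1 fusion, which binds GGAA
microsatellites — maximal runs of consecutive `GGAA` units — and converts
them into de novo enhancers. Binding requires at least 4 consecutive
repeats and is optimal between 15 and 25; alveolar rhabdomyosarcoma's
PAX3-FOXO1 binds the degenerate consensus `ATTWGTCACGGT` instead. A
synthetic cassette placing such an element upstream of a minimal promoter
therefore drives payload expression only where the fusion protein exists:
in tumor cells. This package implements the sequence analysis, design and
statistics that support that program. Everything runs on synthetic data
with known truth; no external downloads are required or used.

## Coordinate and scanning conventions

All interval data are 0-based half-open internally and in BED output; GFF3
is converted at the boundary (1-based closed on disk). The repeat scanner
reports *maximal runs of complete unit copies*: flanking partial copies do
not extend a run, any non-ACGT character breaks a run, and lowercase
(soft-masked) bases are uppercased by default with an option to treat them
as breaks. Runs of the reverse-complement unit (TTCC for GGAA) are reported
as separate, minus-strand records at forward coordinates; for the GGAA/TTCC
pair the two record sets cannot overlap, and the census keeps them separate
rather than merged (the publication's counting convention is not stated, so
strand-annotated separation — the lossless choice — is used). When a
generic unit admits overlapping chains in different phases, the scanner
keeps the chain with more complete copies, leftmost on ties, so output is
deterministic.

## Annotation model

A microsatellite is *bound* when it overlaps a ChIP peak by at least 1 bp
(configurable; the original operationalization of "bound" is not stated).
Context classification uses precedence promoter_proximal > exonic >
intronic > intergenic; the published census only reports promoter-proximal
and intronic/intergenic classes, and the exonic class is added to make the
partition exhaustive. The promoter window defaults to −1000/+100 bp around
the TSS *in gene orientation*, so for a minus-strand gene with TSS t it is
`[t − 100, t + 1000]` in genome coordinates. One TSS is carried per gene
record; multi-TSS genes must be flattened upstream. The TSS interval is gap
semantics — the number of bases strictly between the msat edge nearest the
TSS and the TSS base, 0 on overlap or adjacency — because the measurement
point behind the published minimal interval (49 bp) is not defined; ties in
the census minimum resolve to the smallest gene id.

## Motif repair

Matching is consensus-set membership, not PWM scoring: a mismatch is a base
outside the IUPAC set at that position, which follows the "completely
match" framing of the design work. Repair substitutes only incompatible
positions, so the edit count equals the prior mismatch count, and at a
degenerate position that must change, the alphabetically first allowed base
is chosen (the published syn_alk construct does not say whether A or T was
used at the W; `A` is this package's documented, deterministic choice —
appended exact-motif copies are `ATTAGTCACGGT` for the same reason).

## Cassette assembly and junction guards

Assembly order is enhancer block, spacer, minimal promoter, kozak, then
P2A-linked ORFs. "Directly upstream" is a 0-bp spacer; if the
enhancer/promoter junction would create or extend a repeat run (a promoter
starting with `GGAA`), a 1-bp neutral spacer is inserted automatically (or
an error is raised naming the junction, when auto-spacing is disabled).
Guards re-scan the finished assembly: a GGAA design must contain exactly
one run of the specified count (none for the repeat-free control), and a
PAX3-FOXO1 design must contain exactly the processed base's exact-match
count plus the requested extra motifs, with no repeat run created. Added
motifs are appended 5′ of the base enhancer with a 10-bp neutral spacer;
their placement and spacing in the published constructs are not stated, so
this default is a documented choice. The published YB-TATA, P2A and payload
sequences are not printed either; the shipped defaults are clearly-labelled
synthetic stand-ins (a TATA-containing minimal promoter, the standard P2A
peptide coding sequence, short valid ORFs) and every part is overridable —
the engine's contracts are sequence-agnostic. The ~300 bp base enhancer for
the PAX3-FOXO1 designs (the ALK intron-3 segment, chr2:29,657,671–29,657,976
in hg38) is supplied by the user as sequence; tests use a synthetic stand-in
carrying one near-match with two core mismatches.

Frame validation treats the region from the first ORF through the last ORF
(including linkers) as one CDS: its length must be divisible by 3, it must
start with ATG, and translation must contain exactly one stop, at the
terminal codon — this is what P2A bicistrons require.

## Screen statistics

The published screen ("significantly overexpressed versus any other normal
tissue", 36 genes from 50 tumors vs 928 normal samples in 70 tissue types)
does not state its test, correction or threshold, and its input accessions
are not printed; the printed 36 is therefore not desk-reproducible. The
reimplementation makes the following documented choices: one-sided Welch t
per gene per tissue on log2 intensities (Mann-Whitney available),
Benjamini-Hochberg across the *entire* gene × tissue family (conservative
and deterministic, rather than per-tissue), a call only when every tissue
is cleared (a single failing tissue vetoes), and a fold-change floor of
1 log2 against the *highest* normal tissue. Tissues with fewer than 3
samples are excluded with a warning. These semantics give the veto
monotonicity property (dropping a tissue can only keep or add calls) and
control the empirical FDR in null simulations, both asserted in the test
suite.

## Dose-response model

Viability is modelled as f(x) = d / (1 + exp(b(ln x − ln e))) with the
lower asymptote fixed at 0 — the three-parameter log-logistic named in the
original analysis; b > 0 means response falls with dose and e is the ED50
in µM. Fitting is least squares on ln-dose via bounded L-BFGS-B
(d ∈ (0, 1.5·max response], b ∈ [0.1, 20], e ∈ (0, 10³·max dose]) from
d₀ = max per-dose mean, e₀ = dose nearest d₀/2, b₀ = 1, followed by a
Nelder-Mead polish kept only when it improves the objective inside the box
(this recovers noiseless parameters to ~10⁻⁸ while staying robust on noisy
data). Vehicle rows (dose 0) are excluded from the likelihood and serve as
the normalization reference. Confidence intervals are nonparametric
bootstrap over replicates within dose (default 1000 resamples, seeded) —
more trustworthy than asymptotics at the typical 4 replicates. Curves with
no kill (per-dose means non-decreasing, or an estimate beyond the tested
range) are censored: flagged non-converged with ED50 reported as
"> max dose"; censored fits are excluded (with a warning) from group fold
changes, which are ratios of geometric means.

## The synthetic world

The generators state the world the tests live in; their defaults are the
published conditions wherever those are printed, and field-plausible values
otherwise, fixed once:

* genome: i.i.d. background at GC 0.41 (human-like); planted runs are
  written verbatim and flanked by a single base drawn from outside the
  unit's letter set (C for GGAA, A for TTCC) so background can never extend
  them — this keeps the recorded truth exactly equal to an exhaustive scan,
  and accidental background runs are recorded rather than suppressed;
* peaks: exactly round(bound_fraction × n) runs covered, 20 bp margins,
  jitter bounded by the margin (how "bound" was operationalized originally
  is unknown, so coverage is a dial with exact truth);
* expression: 50 tumor samples, 928 normals in 70 tissue types (13–14 per
  tissue), per-gene baselines uniform on [4, 12] log2 units, Gaussian noise
  SD 0.5 log2 — typical microarray intensity scales; planted genes shift
  tumor samples upward by their effect;
* dose-response: upper 1, slope 1, ED50 0.4 µM (the printed tumor-line
  average), 8 log-spaced doses spanning 0.001–100 µM, 4 replicates, noise
  SD 5% of the upper asymptote. Eight strictly half-log steps from
  0.001 µM would span only 0.001–3.16 µM, contradicting the stated span;
  the span wins (step 10^(5/7)), and recovery is insensitive to this.

What a green test establishes is therefore recovery of *planted* structure
under i.i.d. noise: the generators do not model chromatin context,
correlated probes, batch effects, read-level artifacts, or peak-caller
behavior, so agreement here does not certify performance on real ChIP-seq
or microarray data. The published census fractions (97.7% intronic/
intergenic, 0.4% promoter-proximal, minimal interval 49 bp) and the
36-gene call set depend on unpublished accession lists and annotation
versions; they are covered by planted-truth round trips — a layout built to
those fractions must be summarized to exactly those numbers — not by
re-deriving them from raw data.

## Numerical and degenerate-input choices

* One root seed derives per-generator substreams by a fixed integer hash,
  so all outputs are byte-identical under identical (config, seed).
* Zero bound msats yields NA census fractions with n_bound = 0 rather than
  0/0.
* All-constant expression rows are untestable and dropped with a warning.
* The scanner rejects non-primitive units (e.g. `GAGA`) since their run
  decomposition is ambiguous.
* Repair of minus-strand matches edits against the reverse-complemented
  consensus, choosing the alphabetically first allowed base in
  forward-strand coordinates.

## Known limitations

Peak calling, probe-to-gene collapsing, normalization, enhancer-target
assignment beyond nearest TSS, PWM scoring, 4/5-parameter dose-response
models, and vector-backbone modelling are out of scope. The screen assumes
the input matrix is already log2-normalized and comparable across samples.
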