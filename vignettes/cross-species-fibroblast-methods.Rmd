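---
title: "Methods: cross-species fibroblast transcriptome comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species fibroblast transcriptome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfibro)
```

## The problem

Comparing agonist-induced transcription between dermal fibroblast cultures
of two rodent species — the white-footed deermouse *Peromyscus leucopus*
and the house mouse *Mus musculus* — poses two methodological problems that
ordinary within-species RNA-seq workflows do not solve. First, read counts
aligned to two different reference CDS sets are not directly comparable
across species: library depth, annotation completeness and CDS lengths all
differ. Second, the biological design is paired — each animal contributes
one cell line, split into control and agonist-treated cultures — so the
informative contrast is within a line, not between group means.

`crossfibro` implements the full analysis chain for this design: a
housekeeping-gene ratio normalization for cross-species comparability,
paired fold-change and t-test differential expression, species-specificity
classification, length and expression analyses of endogenous retrovirus
(ERV) and transposable element (TE) repeat classes, and a Kozak-context
open reading frame scanner that asks which transcribed repeats could
plausibly be translated.

## The normalization chain

For cross-species comparison a value must be unitless and
reference-agnostic. The chain is:

1. **Total-count normalization** (`total_count_normalize()`): counts are
   divided by the sample total (CPM scale; the 1e6 factor cancels in every
   downstream ratio).
2. **Per-kilobase adjustment** (`per_kb_adjust()`): division by CDS length
   in kb removes the length advantage of long CDS.
3. **Housekeeping ratio** (`gapdh_ratio()`): division by the same sample's
   Gapdh value (same units, after the same two steps) yields a per-sample,
   per-gene quantity comparable across annotations and species. The
   reference row becomes exactly 1 and ratios between any two other genes
   are unchanged.

The Gapdh denominator is the length-adjusted, total-count-normalized Gapdh
value rather than its raw count: the numerator and denominator must carry
the same units for the ratio to be scale-free. The chain as a whole is
invariant to library depth by construction, which the tests verify
directly.

Within a species, the paired fold-change analysis runs on the
total-count-normalized, length-adjusted values *without* the Gapdh ratio:
the ratio is a cross-species device, and dividing by a noisy denominator
would only add variance to a within-species contrast. TPM (`tpm()`) is used
for expression filtering (features with mean TPM >= 10) and TMM factors
(`tmm_factors()`, computed by edgeR's standard trimmed-mean-of-M-values
procedure) are available where library-composition correction is wanted.
Total-count normalization alone is deliberately *not* composition-robust:
when 10% of features quadruple, every null feature's normalized value
shrinks by ~23%, which is visible in the simulated Gapdh fold change on the
normalized scale while its count-scale paired fold change stays at 1.

## Paired differential expression

Per feature and cell line, the treated/control ratio is formed (with a
pseudocount, default 0.5 on the count scale, applied only when zeros occur
and reported via a message — never silently inside normalization). The
fold change is the **geometric mean** of per-line ratios, so the natural
log of the fold change equals the mean of per-line LN ratios exactly; the
paired t-test is then the one-sample t of those LN ratios against zero
(`paired_t()`), two-tailed, df = lines − 1. Features with zero variance
across lines return `NA` — an explicit undefined flag — and are excluded
from the Benjamini–Hochberg ranking (`bh_fdr()` uses m = number of valid
tests).

A DEG call (`call_degs()`) requires both FC ≥ 2 (or ≤ 0.5) *inclusive* and
p < 0.001 *exclusive*. The FDR bound implied by a fixed p-threshold is
dataset-dependent, so the realized BH q is reported per feature rather than
hard-coding any printed bound. Species specificity
(`classify_specificity()`) requires a ≥ 10× difference between the species'
fold changes, boundary inclusive; the cross-species expression table
(`cross_species_ratio()`) reports Gapdh-scale ratios of species means per
condition with Welch t-tests on LN values. Both readings of the
ten-fold rule (on treatment fold changes and on expression ratios) are
available, and outputs label which rule produced each call.

## The synthetic study

`simulate_paired_counts()` generates the study design: 2 species × 5 cell
lines × {0, 1, 10} µg/mL, negative-binomial counts with mean
`exp(baseline + species offset + line effect + planted effect × treated)`.
Design choices, fixed once:

* **Dispersion** (NB size) defaults to 100, i.e. a biological coefficient
  of variation of 0.1 — the standard figure for replicate cultures of
  genetically homogeneous lines. An analytic power computation (noncentral
  t with df 4 at the two-sided 0.001 level, per-line LN-ratio standard
  deviation `sqrt(2(1/μ + 1/size))`, and the composition shrink of
  total-count normalization) shows this is also the regime in which a
  five-pair design detects a fourfold effect reliably, which is what the
  generator is specified to emulate.
* **Baseline log-means** are uniform on log(50)–log(2000): moderately to
  well-expressed features, where the paired design is meant to operate.
  The real data's dispersion and expression profile are unknown; both
  parameters are exposed in `count_sim_spec()` and documented as choices.
* **The line effect is per-feature**, shared between a line's control and
  treated samples (sd 0.3 on the LN scale). A scalar per-line effect would
  be pure library depth and would vanish under total-count normalization;
  a per-feature effect is the simplest structure under which pairing
  genuinely beats an unpaired split after normalization, which the tests
  check.
* **Gapdh** gets the top baseline, zero treatment effect, and zero line
  effect — planted stability mirroring the near-unity housekeeping fold
  changes the design assumes.
* The planted effect applies at both doses (the dose–response within a
  tenfold range is treated as flat), and planted feature sets are drawn
  independently per species.

`simulate_erv_set()` generates repeat records with log-normal lengths:
`sdlog` defaults to 0.8326 (raw-law skewness ≈ 4, the order observed for
repeat length distributions) and `meanlog` is solved from
`P(length < 500 bp) = 0.9`, so the ≥ 500 bp filter excludes ~90% of
records by construction; lengths are capped at 9,600 bp by resampling.
Sequences are uniform random A/C/G/T, and a chosen fraction of records
receives one planted ORF satisfying the Kozak predicate exactly at its
recorded coordinates (random strand; non-stop sense codons; stop codon
terminated), which gives the scanner a ground truth.

What the generator does **not** emulate: real dispersion heterogeneity,
correlated co-expression modules, multi-mapping ambiguity between repeat
copies, GC or length biases in counting, nested repeats, and non-uniform
background base composition. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the stated statistical
structure, not performance on real libraries.

## ERV/TE analyses

The ≥ 500 bp filter (`filter_min_length()`, inclusive) defines the
reference sets. Z-scores standardize a query against the **complete**
reference set for lengths and against the TPM-expressed subset for
expression; the sample (n−1) standard deviation is used throughout, and
the convention matters for the magnitudes, so it is fixed and documented.
Skewness is the adjusted Fisher–Pearson coefficient (with the
n/((n−1)(n−2)) correction); the upstream convention of printed skewness
values is not stated anywhere we can check, so this choice is documented
rather than asserted to match. `top_k_by_tpm()` breaks ties at the k-th
rank by longer length, then lexicographic id, so outputs are deterministic
across runs. The expression-on-length regression (`ols_with_bands()`) is
ordinary least squares on untransformed TPM versus bp by default (a
log-TPM analysis is a caller-side transform away), with t-based 95%
confidence (LCL/UCL) and prediction (LPL/UPL) bands satisfying
LPL ≤ LCL ≤ mean ≤ UCL ≤ UPL pointwise.

Percentages are rounded half-up (`percent()`), never banker's rounding:
this is the convention that reproduces every printed count/percentage pair
in the tables this pipeline mirrors (21/87 → 24%, 19/21 → 90%,
832/10,843 → 7.7%, 1,136/10,843 → 10.5%, 10,843/103,397 → 10.5%).

The passage contrast (`passage_contrast()`) applies thresholds (|FC| ≥ 4,
mean TPM ≥ 10, FDR < 0.01 for the coding analysis; |FC| ≥ 2, mean TPM ≥ 5,
FDR < 0.01 for repeats) to group-mean TPM, reporting negative log2 FC for
features higher in the second group. The negative-binomial GLM used
upstream of such tables in the original workflow is an off-the-shelf
procedure and is deliberately not re-derived here: the function accepts an
externally supplied FDR column and otherwise falls back to Welch t-tests
on log2(TPM + 0.5) — adequate for threshold application, not a replacement
for a count-model fit.

## The Kozak ORF scanner

`find_kozak_orfs()` scans all three frames of both strands. A hit is an
ORF that (i) starts at ATG with the A at +1, (ii) has a purine (A/G) at
−3 — which requires at least 3 bases upstream on the scanned strand —
and G at +4 (the first base of codon 2, hence always inside the ORF),
(iii) has at least 30 sense codons (ATG included, stop excluded; "codons"
equals the encoded amino-acid count), and (iv) terminates at an in-frame
stop wholly within the sequence. Requiring the stop is a design decision:
"translatable" presupposes a complete frame; a `require_stop = FALSE` flag
admits stop-less terminal ORFs for sensitivity analyses. Two reporting
modes are explicit in every output: `maximal` (default) keeps only the
5′-most qualifying ATG per (strand, frame, stop) segment; `all_starts`
reports every qualifying ATG, and maximal hits are always a subset.
Ambiguity codes at −3/+4 disqualify an ATG; an N inside a candidate ORF
rejects it (translation undefined) and the rejection is counted.

Coordinates are always a plus-strand interval (`start < end`,
`end − start + 1 = 3 × (codon_count + 1)`), with a strand flag; for
minus-strand hits the A of the ATG sits at `end`. This projection makes
hits directly renderable as standard annotation intervals.

The scanner is verified two ways on every test run: equivalence with a
brute-force enumerator that applies the predicate at every (strand,
position) pair of random 2-kb sequences, and a strand-symmetry bijection
(hits on the reverse complement are exactly the strand-swapped hits).

## Numerical and degenerate-input conventions

* Intervals are 0-based end-exclusive (`length = end − start`), the
  convention forced by the printed locus/length pairs this pipeline
  consumes; 1-based inclusive input converts on read.
* Counts must be integers; fractional values are rejected, not rounded.
* Zero-variance t-tests, empty filters and constant skewness inputs
  return explicit `NA` flags, never fabricated values.
* Statistical calibration and recovery runs use 12,000 features × 30
  samples and 4,000 features × 5 seeds respectively — sizes at which the
  Monte-Carlo error of the checked rates is small against their
  tolerances, and the whole suite stays fast.
* The doubling-time estimate `24·log10(2)/slope` is invariant to density
  rescaling; non-positive slopes flag "no growth" rather than erroring.
* Peptide coverage counts unique protein positions (overlapping matches
  via zero-width lookahead, so self-overlapping peptides are handled);
  coverage is order-independent and duplication-idempotent.

## Known limitations

The cross-species ratio inherits every caveat of single-reference-gene
normalization: a condition- or species-dependent shift in Gapdh
transcription would propagate to every gene. Total-count normalization is
not composition-robust (use the TMM factors when that matters). The ORF
scanner asserts translatability context, not translation; its peptide
output is intended for downstream homology search. Repeat expression
analyses operate at the class level: attributing short reads to individual
repeat copies is unreliable and the pipeline does not attempt it.
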