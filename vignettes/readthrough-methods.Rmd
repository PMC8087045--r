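---
title: "Quantifying stop-codon readthrough from ribosome profiling: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stop-codon readthrough from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthroughr)
library(dplyr)
```

## The measurement problem

Translation normally terminates when eRF1 recognises a UAA/UAG/UGA codon in
the ribosomal A site. At low frequency a near-cognate tRNA decodes the stop
codon instead and elongation continues into the 3'-UTR ("readthrough").
Ribosome profiling captures this directly: footprints whose P-sites lie
beyond the canonical stop codon, in reading frame 0 with the CDS. The
package's job is to turn footprint libraries plus transcript annotations
into a per-gene readthrough efficiency and the downstream analyses that ask
which sequence features modulate it.

Three facts about termination-defective libraries shape every design choice
below:

1. Ribosomes queue at start and stop codons when termination slows, so raw
   CDS density is inflated near the edges.
2. Readthrough is in-frame by definition; frameshifting and post-recycling
   reinitiation produce off-frame 3'-UTR footprints that must not count.
3. Readthrough ribosomes terminate (and stall) again at the first
   downstream in-frame stop codon, the end of the "extension" region.

## Transcript geometry

All coordinates are 0-based, half-open, in transcript space; all genomic
conversion happens at load time. The annotated CDS includes its stop codon,
but the analysis uses the *adjusted* convention in which the stop codon
belongs to the 3'-UTR side: `cds_adj` = CDS minus stop, `utr3_adj` = stop +
3'-UTR. Within `utr3_adj`, the **extension** runs from the first nucleotide
after the canonical stop through the first downstream in-frame stop codon
(inclusive of that codon's 3 nt — the geometry is ambiguous in principle, so
`include_downstream_stop = FALSE` switches to the exclusive reading), and
the **distal 3'-UTR** is the remainder. For region labels the canonical
stop's 3 nt are reported as part of the extension flank; a switch
(`stop_in_utr3 = FALSE`) restores the conventional CDS-includes-stop
labeling. Genes whose 3'-UTR contains no in-frame stop keep the whole
post-stop 3'-UTR as extension and carry `has_downstream_stop = FALSE` so
downstream analyses can exclude them.

Transcripts without experimentally mapped UTRs receive default lengths of
97 nt (5') and 173 nt (3') — the 75th-percentile lengths of mapped yeast
UTRs — and are flagged `utr3_annotated = FALSE`. The reference gene set
keeps only annotated genes without same-strand overlap of *more than* 18 nt
(strict inequality: an overlap of exactly 18 is retained; read assignment is
ambiguous beyond that).

## The readthrough-efficiency statistic

For footprints of the retained length classes (20–23 and 27–32 nt), each
read's P-site is its 5' end plus a per-length offset consumed from an
externally estimated offset table; offsets are never estimated here. Frame
is `(psite − utr5_len) mod 3` (floored), so frame 0 in the 3'-UTR means
in-frame with the CDS. Then

$$\log_2 RE \;=\; \log_2\!\left(
  \frac{n^{f0}_{3'UTR} / L_{3'UTR,adj}}{n^{f0}_{CDS,trim} / L_{CDS,trim}}
\right)$$

* **CDS term**: frame-0 P-sites only, excluding the first 15 and last 33 nt
  of the annotated CDS (compensating for queuing; the exclusion is defined on
  the annotated CDS — stop included in the zone — and is switchable).
  Off-frame reads and reads in the exclusion zones provably never change the
  estimate (a metamorphic test asserts this).
* **3'-UTR term**: frame-0 P-sites over the adjusted 3'-UTR (stop + annotated
  3'-UTR; the 3-nt stop is counted in the denominator length by default, and
  the numerator region can be narrowed to the extension with
  `numerator = "extension"`). No exclusion is applied at the downstream stop
  because many extensions are shorter than the exclusion zone; the estimate is
  therefore *knowingly* biased upward when ribosomes pile up there, and the
  synthetic generator reproduces exactly this mechanism so the bias is
  testable rather than hidden.
* **Sentinels, no pseudocounts**: zero trimmed-CDS counts give `NA`
  (undefined), zero 3'-UTR counts give `-Inf` (excluded from ranked
  analyses). Noise control is by expression filtering, not smoothing: genes
  with CDS RPKM < 5 *and* 3'-UTR RPKM < 0.5 are discarded. The wording of
  that rule is genuinely ambiguous between a conjunctive and disjunctive
  reading; the conjunctive reading is the default and the disjunctive one is
  available via `rule = "disjunctive"`.
* **Grouping**: among filtered genes with finite estimates, the top and
  bottom 15% by log2 RE form the High and Low groups
  (`floor(n * fraction)` each, ties broken by gene id for order
  independence).

For premature termination codons, `ptc_readthrough()` uses the ratio of
frame-0 counts strictly downstream vs strictly upstream of the PTC, which
cancels mRNA-abundance differences between samples.

## The feature set

`build_feature_matrix()` assembles one row per gene: stop codon (nt +1..+3),
nt −15..−1 and +4..+9 read off the transcript (positions outside the CDS or
3'-UTR become `NA` and the gene is flagged), the first downstream in-frame
stop identity, P- and E-site codons and residues, and residue-class
fractions over four exit-tunnel windows (upper aa 3–9, constriction aa
10–12, central aa 13–19, lower aa 20–30, indexing from the
peptidyl-transferase-proximal residue). The charge classes are + = K/R/H,
− = D/E, 0 = rest; polarity and the four hydrophobicity classes follow the
Kyte–Doolittle scale binned at 2.8, 1.0 and −3.4; all tables are
user-overridable because the class names do not by themselves fix the
residue assignments. 3'-UTR structure (minimum free energy in a 150-nt
scanning window, structure distance) and lower-tunnel helix fractions are
*consumed* from external predictor tables, never computed. Two negative
controls — a uniform integer 1..100 and a uniform factor over A/C/G/U —
calibrate the importance baseline. Codon optimality (`gene_tai()`) is the
geometric mean of per-codon tRNA adaptation index over the sense codons.

The exact published composition of such feature sets is never recoverable
bit-for-bit from a prose table (fraction groups may or may not count
complements); the packaged schema (`feature_schema()`) is the authoritative
enumeration here: 26 categorical + 45 numeric features.

Missing-value policy: genes with `NA` core sequence features are dropped
(logged); `NA` external features are median-imputed by default or dropped
via config; all-`NA` features are removed.

## Forest models

Both tasks use 100-tree forests with an mtry grid of 1, 11, 21, …, 81
(clipped to the number of features) and 5-fold cross-validation, the best
mtry chosen by mean CV metric. Regression predicts log2 RE and reports
NRMSE (RMSE divided by the per-fold response range); classification
separates High from Low and reports AUROC (rank-sum formulation, ties = ½).
Folds are stratified for classification to guard small fixtures.

Feature importance (%IncMSE for regression, MDA for classification) is
computed by *explicit out-of-fit permutation* on each held-out fold
(`n_repeats = 5`), not by the forest's out-of-bag machinery: the estimator
is implementation-portable and its assumptions are visible. MDA is reported
as the percentage-point increase in misclassification because the baseline
error can be zero, making a ratio undefined. Absolute magnitudes of
permutation importance depend on the estimator; only *rankings* (in
particular, informative features vs the negative controls) are treated as
meaningful, and the tests assert rankings, never magnitudes.

## Context-enrichment battery

* `group_median_shifts()`: per feature level, the group median log2 RE minus
  the overall sample median, with a two-sample Wilcoxon rank-sum test of the
  level vs all remaining genes. "Wilcoxon's rank sum test" names the
  two-sample test, but comparison "to the sample median" could also mean a
  one-sample signed-rank test, so both are shipped
  (`variant = "signed_rank"`). Note the effect statistic is attenuated when
  a level holds a large share of the sample — the overall median moves with
  it — which is inherent to the definition, not a bug.
* `high_low_enrichment()`: chi-square goodness-of-fit of each group's level
  counts against reference frequencies, Bonferroni-corrected over the number
  of positions tested (the family is configurable since it could plausibly
  span positions, levels, or samples); per-level log2(group/reference)
  fractions; absent levels flagged `zero_observation` (no log2 value, grey
  tiles in `autoplot()`).
* `association_residuals()`: chi-square independence test with per-cell
  Pearson residuals `(O − E)/√E` (the standard residual output of chi-square
  routines; positive = attraction, negative = repulsion), warning whenever
  any expected count is below 5.
* `spearman_cor()` / `correlation_matrix()`: tie-corrected rank correlations,
  pairwise-complete over `NA`; `translation_efficiency()` is ribosome
  density over expression.

## The synthetic generator

`synthetic_config()` + `generate_transcriptome()` + `assign_true_re()` +
`simulate_footprints()` emulate the phenomena the estimator must survive:
3-nt periodic CDS coverage (Poisson, uniform within the region's codon
grid), per-gene frame-0 3'-UTR density `lambda * 2^true_log2_re`, partial
frame fidelity past the stop, off-frame CDS noise, a guaranteed first
downstream in-frame stop, and optional stall pile-ups at the penultimate
codon and the downstream stop (`stall_multiplier`); each read's 5' end is
back-computed through the offset table, so the full P-site assignment path
is exercised. True RE is additive on the log2 scale: baseline + feature
effects + gene noise.

Defaults are fixed once as a realistic termination-competent yeast-like
library: stop frequencies UAA 0.47 / UAG 0.23 / UGA 0.30 (yeast usage),
nt +4 mildly G/A-biased (A 0.30, C 0.20, G 0.30, U 0.20), baseline log2 RE
−4 with sd 1 (basal readthrough of order 10^-1.2 %–1%, spanning the
reported 100-fold between-mRNA range), frame fidelity 0.7 in the 3'-UTR
(frame 0 dominant in the extension but visibly noisier than the CDS),
off-frame CDS noise 0.05, `stall_multiplier = 1` (raise to ~20 to emulate
termination/recycling mutants, which produces the expected penultimate-codon
metagene peak), read lengths peaked at 28 nt over the 20–23/27–32 classes,
and a synthetic offset table (20–23 nt → 10/10/11/11; 27–32 nt →
12/12/13/13/14/14).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: sequence-dependent ligation/amplification bias,
nuclease trimming heterogeneity, multi-mapping, UTR mis-annotation,
NMD-coupled mRNA decay, or any correlation structure between features other
than the programmed effect map and the optional stop↔nt+4 odds coupling.
Recovery results on synthetic data bound the estimator's statistical error,
not its robustness to annotation or library-preparation artifacts.

## Numerical and testing choices

* Problem sizes: the property suite uses 300,000 uniform P-sites for the
  frame-fraction check (binomial sd ≈ 0.0009, comfortably inside the ±0.01
  band), 1,000 genes at CDS frame-0 density 8 reads/nt for RE recovery
  (Spearman ρ ≥ 0.9 and median |error| ≤ 0.3 log2 units on genes with ≥ 50
  frame-0 3'-UTR reads — the guarantee is conditional on coverage, so it is
  asserted on the well-covered genes), 800 genes with injected effects
  (UGA +1.5, UAA −1.0, nt+4 C +0.8 log2 units) for forest recovery, a
  20-seed label-permuted null for AUROC calibration, and 2,000 genes for the
  context-statistics recovery.
* Determinism: every stochastic routine takes a seed, saves and restores the
  caller's RNG state, and derives internal seeds explicitly, so the full
  train→importance path is reproducible bit-for-bit.
* Degenerate inputs are errors, not silent results: zero-range responses in
  NRMSE, single-class AUROC, constant vectors in Spearman, single-level
  contingency tables, all-identical RE values in grouping, out-of-range
  P-sites.
* Ties: High/Low boundaries break ties by gene id; AUROC uses midranks;
  Spearman uses tie-corrected ranks with the asymptotic two-sided p.

## Known limitations

The estimator inherits the documented upward bias where downstream-stop
pile-ups fall in frame 0 inside the numerator; the package measures it
(toggling `stall_multiplier` 1→20 shifts the median estimate upward by a
bounded, tested amount) rather than correcting it. Reinitiation within a
few nt of the stop lands in frame 0 with probability ~1/3 and is
indistinguishable from readthrough at the footprint level; interpretation
on recycling-mutant data should account for this. The RPKM filters and the
High/Low fractions are conventions, not optima; both are parameters.
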