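---
title: "An integrated plasma epigenomic score for fusion-driven renal cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated plasma epigenomic score for fusion-driven renal cancer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `cfties`, the choices
made where the design was genuinely open, and what the synthetic study
design does and does not establish. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Translocation renal cell carcinoma (tRCC) is driven by a *TFE3* gene fusion
that acts as an oncogenic transcription factor. The tumor is mutationally
quiet — few recurrent point mutations, often minimal copy-number change —
so mutation- and copy-number-based ctDNA assays have little to grab onto,
and the breakpoint itself varies too much across patients for a universal
targeted assay. What the fusion does do, reliably, is activate a
characteristic set of regulatory elements. Those elements carry active
histone marks (H3K4me3 at promoters, H3K27ac at promoters and enhancers) in
tumor chromatin, tumor chromatin circulates in plasma as nucleosome-bound
cfDNA fragments, and cell-free ChIP-seq (cf-ChIP) recovers those fragments
mark by mark. The package turns this observation into a score: quantify
plasma cf-ChIP signal at cell-line-derived, fusion-specific site sets, and
sum it into one number per sample.

## Coordinates and interval semantics

All coordinates are BED-convention 0-based half-open. Two intervals overlap
when they share at least one base pair; a shared boundary
(`end(a) == start(b)`) is not an overlap — the same convention as BEDTools,
which defined the overlaps in the original region sets. The center of an
interval is `floor((start + end) / 2)`, which is deterministic for
even-width intervals. Merging (consensus peaks, flank extension) is the
union of covered ranges on the integer line, so book-ended intervals merge.
Exact duplicate records are dropped at construction and zero-length records
rejected; peak inputs in the wild contain both, and neither carries
information for this analysis.

## Signature derivation

Three site sets form the signature:

1. **H3K4me3 tRCC-up sites** and 2. **H3K27ac tRCC-up sites**: differential
   peaks between tRCC and ccRCC cell-line panels over a merged consensus
   peak set, selected at FDR-q < 0.01 with log2FC > 2 (H3K4me3) or > 1
   (H3K27ac), tRCC-enriched direction only.
3. **Fusion-occupied TFBS**: known TFE3 binding sites (database catalog)
   that overlap ≥ 1 bp with the merged union of fusion ChIP-seq peaks from
   tRCC cell lines, keeping the catalog coordinates.

Because signal at sites present in both set 2 and set 3 would otherwise be
counted twice in the integrated sum, TFBS overlapping any H3K27ac up site
are removed from set 3 at bundle assembly. In the synthetic generator, 13%
of TFBS are constructed to overlap the H3K27ac set so this deduplication is
always exercised; the fraction matches the shared-site proportion observed
in the real catalogs this design emulates.

### The differential test

Counts are normalized to counts-per-million with a 0.5 pseudocount; the
reported log2 fold change is the log2 ratio of group mean CPM. The per-peak
p-value is limma's empirical-Bayes moderated t on log2-CPM (limma-trend),
adjusted by Benjamini–Hochberg across all consensus peaks of the mark.

The moderation matters and is a deliberate choice. With a handful of cell
lines per group (the emulated design is 4 tRCC vs 6 ccRCC), a per-peak
Welch t has ~6 degrees of freedom; even a true 8-fold change cannot
routinely produce p-values below the BH threshold that q < 0.01 demands, so
an unmoderated test caps recovery near 40% regardless of effect size.
Sharing the mean-variance trend across peaks restores the degrees of
freedom and is exactly what the count-GLM tools used on such designs
(DESeq2/edgeR behind DiffBind) do implicitly. The test suite verifies, at
the simulated design (negative-binomial counts, dispersion 0.1, log2FC = 3,
200 peaks with 20 spiked), ≥ 90% recovery with zero false positives under
the joint q/log2FC filter, and ≤ 1% selection under a pure null.

One caveat this design surfaces: with CPM normalization, spiked peaks
inflate the tumor group's library size, shifting all log2FCs down by
log2(library ratio) — a composition bias that median-of-ratios
normalization would remove. The non-differential background peaks in the
consensus universe (600 by default) keep this shift modest (~0.6), and the
thresholds are applied to the shifted estimates, as they would be in
practice.

## Plasma quantification

Each fragment is collapsed to its 1-bp midpoint, so a fragment can count at
most once per site before window resizing. Each signature site is resized
to a 3-kb window centered on the original site and divided into 75 bins of
40 bp; midpoints are assigned to bins by offset from the window start and
summed across sites into one aggregate profile per (sample, site set). A
midpoint falling in two overlapping resized windows counts once per window;
with the deduplicated, well-spaced site sets this is rare, and it keeps the
operation exactly checkable against a per-site loop.

**Shoulder normalization.** The background level is the mean bin count over
the outermost 20% of bins on each side (bins 0–14 and 60–74); the central
signal is the sum over the middle third (bins 25–49, ± 500 bp) of
background-subtracted counts floored at 0 per bin. The geometry is
configurable; the defaults put the central region wide enough to cover the
original site (≤ 1 kb) and the shoulders fully outside it. Subtraction (not
division) is used so that an additive flat background cancels exactly —
a property the tests assert bin-for-bin. Flooring at 0 per bin prevents
noise-driven negative signals; it introduces a small positive bias for
near-empty profiles, which the DHS normalization below divides away in
relative comparisons.

**Housekeeping (DHS) normalization.** The same machinery applied to a set
of ubiquitously active DNase-hypersensitivity sites gives a per-sample
reference; site signals are divided by it. Because both numerator and
denominator are linear in fragment count, the ratio is invariant to
sequencing depth (asserted exactly under sample duplication). A sample
whose reference signal is not positive cannot be normalized and raises a
typed error (`cfties_unquantifiable`) rather than silently scoring zero.
The normalization is applied to the aggregate rather than per bin; for the
ratio-of-sums summary used here the two are equivalent.

## The integrated score

The three component signals are summed unweighted and log-transformed:
`TIES = log(max(s_K4 + s_K27 + s_TFBS, ε))` with ε = 1e-6, needed because
shoulder subtraction can yield exactly 0 for signal-free samples. The log
base defaults to natural log and is configurable; any base is a strictly
increasing transform, so AUC, Youden ordering and rank-test results are
base-invariant (tested), and only the absolute value of a cutoff depends on
it. Optional component weights are not exposed: an unweighted sum is the
simplest defensible combination, and the classifier layer is
transform-invariant anyway.

Classification uses rank-based AUC (Mann–Whitney with ties counted ½,
verified against an all-pairs oracle to 1e-12), Youden's J = TPR − FPR
maximized over midpoint-plus-sentinel thresholds with the rule
`score > threshold → positive`, and leave-one-out cross-validation pooling
held-out predictions. Among equal-J thresholds the largest is chosen,
favoring specificity — the operating regime a rule-out liquid-biopsy test
wants. The reported `mean_threshold` is the arithmetic mean of per-fold
Youden cutoffs.

## In silico dilution and the limit of detection

For each tumor × healthy pair, the read budget is
`N = min(|tumor|, |healthy|)`; `round(N·DL)` fragments are drawn without
replacement from the tumor sample and `round(N·(1−DL))` from the healthy
sample, for eleven dilution levels DL ∈ {0.9, 0.8, …, 0.1, 0.05, 0.01}.
`DL` is defined as the tumor fraction of reads, so the expected tumor
fraction of a mixture is `TF_tumor × DL` — the only reading under which the
expected-TF bookkeeping is coherent when the healthy sample happens to be
the smaller one. Each (pair, DL) is mixed once, deterministically per seed;
both marks are diluted at the same DL. Mixtures are binned by expected TF
into 0.4%-wide bins with open terminal bins (< 0.4%, > 3.2%), and each
bin's pooled scores are compared with the undiluted healthy scores by
two-sided Wilcoxon rank-sum. The limit of detection is reported as the
lowest-TF bin that is significant (p < 0.05) with all higher bins also
significant — an interval, not a point estimate. Tumor samples enter the
experiment only if their tumor fraction exceeds 3%, the inclusion rule of
the design this emulates.

## Longitudinal monitoring

For each patient with multiple draws, the percent change in score between
consecutive draws, `100 · (TIES₁ − TIES₀) / |TIES₀|`, is attributed to the
clinical status of the interval (taken from the later draw). Stable and
response intervals are pooled as the comparator against progression
intervals (Wilcoxon rank-sum). Because the score lives on a log scale and
can approach the ε floor, pairs whose baseline magnitude is below 10·ε are
excluded with a log message — percent change is not meaningful at a
floored baseline.

## The synthetic study design

The generator emulates exactly the statistical structure the analysis
assumes, with defaults chosen once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| genome | one 10-Mb chromosome | placement universe |
| site sets | 60 / 100 / 100 / 200 / 80 | K4-up / K27-up / TFBS / DHS / ccRCC-up |
| TFBS∩K27 fraction | 0.13 | shared-site proportion, exercises dedup |
| background peaks | 600 | non-differential consensus padding |
| site widths | 200–1,000 bp uniform | peak-scale features |
| λ (enrichment) | 20 | site-localized midpoint density vs background for tumor-derived fragments |
| DHS λ | 20 | housekeeping rate, shared by all samples |
| depth | 100,000 fragments/sample/mark | scaled-down cf-ChIP library |
| fragment length | 167 ± 20 bp, floor 60 | mononucleosomal cfDNA |
| tumor fraction | log-uniform 0.005–0.30 (tRCC, ccRCC); 0 (healthy) | spans detectable to marginal |
| NB dispersion | 0.1 | cell-line count noise |

A fragment is tumor-derived with probability TF; tumor-derived fragments
localize to the label's signature sites with probability
`λW / (λW + (G − W))` (W total signature width, G genome size), otherwise
uniform background. ccRCC samples draw tumor fractions like tRCC but enrich
their own comparator site set, so tRCC-vs-ccRCC discrimination is a real
subtype contrast rather than tumor-vs-nothing. All randomness flows from
one master seed through named substreams per sample, making every fixture
byte-reproducible; generator promises are forced before seeding so
call-site expressions cannot perturb the stream.

There is no published value for λ in plasma; the default was chosen once as
a realistic strong-enrichment regime, and under it the synthetic dilution
experiment's detection limit lands in the sub-1% tumor-fraction range. That
is a property of the synthetic calibration, not an inference about patient
data.

**What passing tests show — and don't.** The suite establishes that the
machinery is correct (interval ops, binning, normalization algebra,
classifier statistics all match independent oracles) and that the pipeline
is discriminative end to end at the chosen effect sizes (AUC ≥ 0.9 for
tumor vs healthy at default λ; chance-level AUC under a zero-tumor-fraction
null). It does not reproduce patient-data performance: real cfDNA has GC
and mappability bias, copy-number structure, inter-patient signature
heterogeneity, and tumor fractions estimated with error, none of which the
generator models. Cohort sizes in tests (e.g. 15/15/9) and the acceptance
run (15/12/9 plus three longitudinal patients) are the package's chosen
problem sizes for a desk-scale study.

## Numerical and degenerate-input policy

* Thresholds: candidate cutoffs are midpoints between distinct sorted
  scores plus sentinels beyond the extremes; ties in J resolve to the
  largest cutoff.
* Wilcoxon: exact for small samples without ties, normal approximation with
  tie/continuity correction otherwise (`stats::wilcox.test`).
* Single-class inputs to ROC/Youden/LOO-CV are errors, as is any LOO
  training fold containing one class (the fold is named).
* Missing assays: a sample lacking one mark fails scoring by default; with
  `allow_partial = TRUE` it is scored on available components, the missing
  component recorded as `NA` and the omission messaged.
* Empty site sets are errors at profiling; empty fragment sets raise the
  unquantifiable condition at normalization.
* Zero-clipping: resizing clips the window start at 0 (and at chromosome
  length when sizes are supplied) without shifting the end, preserving the
  bin ↔ offset correspondence.
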