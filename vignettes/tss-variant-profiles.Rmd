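---
title: "Methods: TSS-anchored variant distribution profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS-anchored variant distribution profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssvar)
```

## The problem and the model

Regions flanking transcription start sites concentrate regulatory sequence,
elevated GC content, and transcription-coupled mutagenesis and repair. The
frequency spectrum of the variants found there carries a time axis: rare
alleles are young and sit close to the mutational process, common alleles
are old and have been filtered by drift, selection and GC-biased gene
conversion (gBGC). This package profiles variants of four MAF classes on a
fixed grid around TSSs and asks, bin by bin, where each class deviates from
uniform placement; it then relates those deviations to nucleosome occupancy,
conservation (GERP), gBGC tracts and deleteriousness (CADD) scores.

### The bin grid

Each TSS anchors 200 bins of 50 bp spanning 10 kb, indexed
j ∈ {−100..−1, +1..+100}. Offsets are measured in the direction of
transcription: for a minus-strand TSS the genomic left is downstream. Bin j
covers offsets d ∈ [(j−1)·50, j·50) for j > 0 and d ∈ [j·50, (j+1)·50) for
j < 0, so d = 0 (a variant exactly at the TSS) belongs to bin +1 and the
grid covers d ∈ [−5000, 5000). Half-openness in offset space makes the
reflection symmetry exact: mirroring every coordinate through a point and
flipping strands reproduces every profile bit for bit (a test asserts
maximum absolute difference 0).

Two grid-level conventions worth stating:

* The TSS point is the table's `start` coordinate regardless of strand; the
  source track stores single positions, and no strand-specific `end` rule is
  applied.
* TSSs closer than 5,000 bp to a chromosome end are dropped with a warning
  rather than given truncated windows, so every retained TSS has 200
  complete bins.

### Per-TSS normalization and the uniform null

The bin variant frequency uses a per-TSS normalization:
f(i,j) = vars(i,j)/V(i), where V(i) is the TSS's window total for the class.
TSSs with V(i) = 0 carry no frequency information for that class and are
excluded. This normalization has two consequences that the inference relies
on: the profile sums to exactly 1 across bins, making the uniform-placement
expectation exactly 1/200 with no estimated baseline; and each bin has n
per-TSS observations, giving the one-sample t-test its standard error. The
per-bin test is two-sided against 1/200 with Bonferroni correction over 200
bins at the global α = 0.001. Bins whose f values are constant across TSSs
have no variance to test against; their p is recorded missing and flagged
(`zero_variance`) rather than silently set to 1.

BVF-delta is the paired difference f_rare(i,j) − f_common(i,j) over TSSs
carrying both classes, tested against 0 the same way. The sign convention
(rare minus common) makes positive values mean "young variants
over-represented", the direction expected under purifying selection at
functional sites; swapping the inputs negates every mean and leaves every
p-value unchanged, which is asserted as an invariant.

### Track statistics

Nucleosome (BNP) and GERP (BGS) signals are aggregated as pooled base means:
Σ_i score(i,j) / Σ_i n(i,j) over scored bases. The pooled form is robust to
sparse tracks, where a per-TSS mean would divide by zero for many cells; the
per-TSS bin values are still materialized (`bin_value_matrix()`) because the
CGI-vs-nCGI per-bin t-tests operate on them. gBGC coverage (BBS) is the
per-TSS fraction of the 50 bin bases inside a tract, averaged over all TSSs
with absent cells counted as zero — a quantity in [0, 1] by construction.
CADD (BCS) is the pooled mean of per-variant raw scores per bin and class.

Whole-signal CGI vs nCGI contrasts run a per-bin two-sample t-test (Welch by
default) and combine the 200 raw p-values with Fisher's method. The
combination treats the bins as independent; adjacent bins of a smooth signal
are not, so the combined p is interpreted as a summary score rather than an
exact tail probability, and the run log records this caveat. Underflowed
per-bin p-values are floored at 1e-300 before taking logs, since Fisher's
statistic is undefined at p = 0.

### The window split

For each candidate half-width i = 2..98, r_in(i) correlates BBS with
BVF-delta over bins |j| ≤ i and r_out(i) correlates BGS with BVF-delta over
the complement; the boundary j* maximizes |r_in · r_out|, taking the
smallest i on ties. The tie-break is deliberate: with flat traces the
smallest candidate is the most conservative inner region. Candidates where
either correlation is undefined (fewer than 3 complete pairs, or a constant
vector) get a missing product; if every candidate is missing the procedure
errors. Because a handful of bins can produce spuriously large correlations,
the result is flagged `weak_inner_signal` when |r_in(j*)| < 0.2.

### Other inferential components

* `pearson_test()` reports r, t = r√(n−2)/√(1−r²) and the two-sided t
  p-value; perfectly collinear inputs give t = ±Inf and p = 0.
* `bcs_class_anova()` is the classic equal-variance one-way ANOVA per bin.
  Degenerate inputs follow fixed conventions: identical constant scores in
  all classes give F = 0, p = 1; zero within-group variance with distinct
  group means gives p = 0; a bin with fewer than two populated classes
  (each needing ≥ 2 scores) is missing.
* `wilcoxon_updown()` uses the exact rank-sum distribution for tie-free
  samples up to 20 per side, an exact permutation enumeration for tied
  samples with at most 16 combined observations, and otherwise the normal
  approximation with continuity and tie correction.
* The D'Agostino skewness test implements the 1970 normalizing
  transformation of sample skewness directly and requires n ≥ 8, below
  which the transformation is invalid.
* Bonferroni adjustment is min(1, p·m) with m = 200 for every bin family.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_tss_score` | 20 | confidence score | conservative TSS selection cutoff |
| `rare_threshold` | 1/(2·1092) ≈ 4.579e-4 | MAF | single heterozygous carrier in a 1092-individual diploid panel; `n_individuals` is configurable |
| `common_threshold` | 0.01 | MAF | canonical common-variant cutoff (strict >) |
| mid1/mid2 split | data median | MAF | equal-sized intermediate classes; left-closed at the median, ties to mid1 |
| `alpha` | 0.001 | — | global significance level for every family |
| bin width / count | 50 bp / 200 | — | fixed grid; sub-bin resolution is out of scope |
| `half_window` (multi-TSS exclusion) | 5000 | bp | a region "hosts" another TSS if it lies within ± half_window, judged against the full pre-exclusion list |

The rare threshold deserves one note: 1/2184 = 4.5788e-4 is often quoted
rounded as 4.59e-4. The two values classify identically on any MAF
attainable from 2,184 chromosomes (the next attainable MAF above 1/2184 is
2/2184), so the package uses the exact fraction.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults describe a study of ~2,000 TSSs (half inside
CpG islands) with ~95 variants per 10 kb window split
rare/mid1/mid2/common ≈ 20/22/22/31 — the class shares seen in large human
panels. Planted structure, all recoverable by the pipeline:

* a 1.7-fold rare-class intensity modifier over bins +1..+4 (the first 200
  transcribed bp);
* a rare/common asymmetry of amplitude 0.35 with an inner piece
  −cos(πj/14) over |j| ≤ 14 (a common-variant excess peaking at the TSS
  that flips to a rare excess at the inner edges) and a slow outer wave.
  The inner shape is deliberately non-degenerate at the boundary — a shape
  vanishing there would make the split boundary unidentifiable;
* gBGC tract coverage negatively coupled to the inner delta (high coverage
  where common variants accumulate), GERP positively coupled to the outer
  delta, nucleosome signal positively coupled to the rare-class intensity —
  coupling strengths sized to give bin-level correlations of roughly
  0.7–0.95;
* CADD raw scores with class means decreasing from rare (0.9) to common
  (0.3) and a distance decay of 8e-5 per bp;
* allele-count pairs built as (minor, 2184 − minor) so MAF recomputation and
  all selection filters round-trip exactly.

Chromatin architecture differs by CpG context: CGI promoters get a
nucleosome-depleted region and an upstream conservation dip, nCGI promoters
a downstream occupancy peak, so the CGI-vs-nCGI contrasts have a real
planted difference. `null_model = TRUE` removes every modifier, coupling and
class effect (including CADD class means), producing a fully uniform bundle.

Deliberately not emulated: linkage disequilibrium between variants, sequence
context (tracks are generated directly rather than from simulated sequence —
`predict_cgi()` is validated on constructed strings instead), multi-allelic
sites, overlapping TSS clusters (default spacing keeps windows disjoint),
and chromosome-scale heterogeneity. Passing tests therefore demonstrate
correctness of the statistical machinery on data satisfying the model's
assumptions, not robustness to the correlation structure of real genomes.

## Numerical choices and known limitations

* Profile TSVs print 15 significant digits so a write/read round-trip
  reproduces values to at least 12 significant digits; missing cells are
  `NA`.
* Overlapping bedGraph records resolve deterministically last-one-wins in
  file order, with a warning — reproducible, though order-dependent.
* Maximal-scoring CpG-island segments are extracted top-down (best segment,
  then the flanks), with ties broken toward the smallest start and then the
  smallest end; the O(L²) enumeration oracle in the test suite applies the
  same rules, making the dual-route comparison exact.
* **Calibration of the uniform-null bin test at low counts.** With 10
  variants per window the expected count per bin is 0.05 and the per-TSS
  fractions are extremely discrete; the t statistic of such right-skewed
  data is left-skewed, and the extreme depletion tail is heavier than the
  Student reference. The calibration suite measures a family-wise error of
  roughly 0.015–0.02 at α = 0.001 with Bonferroni under these conditions
  (against ~0.001 for a perfectly calibrated test). The effect shrinks with
  realistic variant densities (~100 per window) and larger TSS counts.
  Conclusions about *depletion* in sparse settings should lean on effect
  sizes and the confidence bands, not the Bonferroni flags alone.
* Test problem sizes are chosen to make the statistical checks sharp but
  quick: null calibration over 200 datasets of 2,000 TSSs; planted-fold
  recovery at 5,000 TSSs; split recovery over 20 replicates of 500 TSSs
  with the two extreme classes only (the mid classes contribute nothing to
  BVF-delta).

## Session info

```{r}
sessionInfo()
```
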