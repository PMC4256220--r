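# tssvar

Profiling how single-nucleotide variants of different minor-allele-frequency
(MAF) classes distribute across the 10 kb region flanking human transcription
start sites (TSSs), and testing which forces — mutation coupled to nucleosome
occupancy, purifying selection, GC-biased gene conversion (gBGC) — shape that
distribution.

The package is aimed at population and regulatory genomicists who have
UCSC-style tables of TSSs and dbSNP-style variant tables plus per-base score
tracks (nucleosome occupancy, GERP conservation, gBGC tracts, CADD
deleteriousness scores), and want a tested, reproducible implementation of
the TSS-anchored bin statistics rather than one-off scripts.

## The statistics

Every analysis lives on a strand-aware grid of 200 bins of 50 bp around each
TSS, indexed j = −100..−1, +1..+100 (no bin 0; positive j is downstream in
the direction of transcription, and a variant exactly at the TSS falls in
bin +1).

* **BVF** (bin variant frequency). For TSS *i* with V(i) variants of a class
  in its window, f(i,j) = vars(i,j)/V(i); BVF(j) is the mean of f(i,j) over
  TSSs. Σ_j BVF(j) = 1, so uniform placement gives exactly 1/200 per bin.
  Each bin is tested against 1/200 with a two-sided one-sample t-test and
  Bonferroni correction over the 200 bins (α = 0.001).
* **BVF-delta** = BVF_rare − BVF_common, computed as a paired per-TSS
  difference and tested against 0 the same way. Positive values mark bins
  where young (rare) variants are relatively more frequent than old (common)
  ones — the footprint of selection or gBGC.
* **BNP / BGS** — pooled bin-average nucleosome and GERP scores:
  Σ_i score(i,j) / Σ_i (scored bases in bin). **BBS** — per-TSS fraction of
  the 50 bin bases inside a gBGC tract, averaged over TSSs. **BCS** — mean
  per-variant CADD raw score per bin and frequency class.
* **Whole-signal contrasts** (CGI-TSSs vs nCGI-TSSs): per-bin two-sample
  t-tests combined with Fisher's method, X = −2Σ ln p ~ χ²(400).
* **Window split**: for candidate half-widths i = 2..98, correlate BBS with
  BVF-delta on bins |j| ≤ i and BGS with BVF-delta on the complement; the
  boundary j\* maximizes |r_in · r_out|, separating an inner gBGC-dominated
  region from an outer selection-dominated region.

A first-class synthetic-data generator (`generate_dataset()`) emits every
input dialect with planted, recoverable effects — a 1.7-fold rare-variant
peak over the first four downstream bins, a 14-bin (700 bp) inner region
with gBGC coupling, nucleosome–rare-variant coupling — so the whole pipeline
is testable end to end.

## Worked example

```r
library(tssvar)

cfg    <- synthetic_config(seed = 42, n_tss = 400)
bundle <- generate_dataset(cfg, dir = tempfile())   # writes the file bundle
result <- run_tss_pipeline(pipeline_config(paths = bundle$paths))
pipeline_report(result)
```

```
TSSs analysed: 400 (CGI 203 / nCGI 197)
Variants kept: 38,144 of 38,144
Class counts: rare=8336, mid1=8771, mid2=8758, common=12279
Variant density in windows vs rest: 0.009535 vs 4.854e-06
...
Rare-class downstream(+1..+4)/upstream(-4..-1) fold, CGI: 1.69
BNP~BVF correlation CGI/rare: r=0.777 t=17.38 p=1.08e-41 n=200
BNP~BVF correlation CGI/common: r=-0.803 t=-18.95 p=2.26e-46 n=200
CGI vs nCGI BNP (Fisher over 200 bins): X2=22627.9 df=400 p=0
Window split boundary: 14 bins (700 bp); inner BBS~delta r=-0.878, outer BGS~delta r=0.908
```

Reading the output: the rare-class fold of 1.69 recovers the planted 1.7-fold
enrichment over the first 200 transcribed bp; the nucleosome profile
correlates strongly and positively with the rare-variant profile (r ≈ 0.78)
and negatively with the common one; and the split procedure recovers the
planted 700 bp inner region where BVF-delta tracks gBGC coverage rather than
conservation. `glance(result)` returns the headline row as a tibble;
`tidy()`/`glance()` methods exist for the test objects, and
`autoplot()` draws any profile, test or split trace, e.g.
`autoplot(result$bvf$CGI$tests$rare)`.

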