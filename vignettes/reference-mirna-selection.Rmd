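---
title: "Selecting and validating stable reference miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating stable reference miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabref)
```

## The problem

qPCR quantification is always relative to a reference transcript, so the
reference must be stable across exactly the conditions being compared. For
miRNAs under stress (heat, UV, hypoxia) no universally accepted references
exist, and borrowing protein-coding housekeeping genes is not an option:
their RNAs are processed, sized and reverse-transcribed differently.
`stabref` implements a discovery-then-validation workflow: candidate
references are mined from genome-wide small RNA-seq as the miRNAs that move
least between stress and control, then validated on the qPCR side with an
independent stability statistic (geNorm) computed on efficiency-corrected
relative quantities.

## Discovery arm: the count model

**Normalization.** Raw counts are scaled per sample by
`total_j / mean(totals)`, so every library sums to the mean raw library
size. This is total-count normalization; it assumes the global miRNA output
is comparable between libraries and that differential miRNAs roughly cancel.
A pseudocount of 10 is added *only* before the log2 transform — it
stabilizes the log for near-zero counts but must not inflate the linear
reads used by the abundance filter.

**Fold change as a slope-1 residual.** For each stress/control pair the
log2 values are fitted with a fixed-slope-1 line; the only free parameter is
the intercept, whose least-squares value is `mean(y − x)`. Any residual
library-size mismatch survives total-count normalization as a constant log2
offset, and the intercept absorbs exactly that. A miRNA's residual is its
bias-corrected log2 fold change, converted to percent variation as
`(2^|r| − 1) × 100`.

**Stability filter.** Defaults follow the workflow this package implements:
variation at most 7% in every designated comparison of a condition group,
and at least 500 normalized reads in *every* sample of the group. Three
choices here were genuinely open and are worth stating:

* *Which variation metric.* Percent variation is computed from the residual
  by default (`variation_metric = "residual"`), because the intercept
  correction is the point of the slope-1 fit; the naive
  `|N_a − N_b| / N_b × 100` on normalized reads is available as
  `variation_metric = "direct"` for comparison. With a residual metric and
  very few miRNAs the intercept itself is poorly pinned — a two-gene matrix
  where one gene moves 20% drags the other gene's residual with it; with
  realistic panel sizes (dozens to hundreds of miRNAs) the intercept is
  anchored and the two metrics agree closely.
* *Raw or normalized floor.* The 500-read floor is applied to normalized
  linear reads, in every sample of the group — the strictest reading, so a
  single low-coverage library cannot smuggle in a quiet miRNA.
* *Group design.* Condition groups with more than two samples (e.g. a
  mutant plus wild type under the same stress) take an explicit list of
  pairwise comparisons; a miRNA's variation is the maximum over them.

Stable sets are intersected across conditions with a full disjoint Venn
partition, and candidates are tiered (low/medium/high) by mean normalized
reads — default boundaries 2,000 and 100,000 reads, chosen so the tiers
match the spread seen in typical worm small-RNA libraries (hundreds to
~400,000 reads); values exactly on a boundary go to the higher tier.

## Validation arm: efficiency and geNorm

**Efficiency.** `fit_efficiency()` regresses Cq on log10(dilution factor).
Working with dilution *factors* (not concentrations) makes the slope
positive, so `E% = (10^(1/slope) − 1) × 100` applies as printed; a negative
slope triggers a warning because it almost always means the input used the
opposite convention. R² is computed directly as 1 − SSE/SST. At least three
distinct dilutions are required; replicate wells enter as individual points.

**Relative quantities.** Technical replicates are averaged on the Cq scale,
then `Q = (1 + E/100)^(Cq_ref − Cq)` with the gene's minimum mean Cq as
reference, so the most abundant sample scores 1 and everything else is
below. Whether min or mean Cq anchors the reference is irrelevant
downstream: every geNorm statistic is built from log-ratios and is provably
invariant to per-gene rescaling (the test suite asserts this on random
matrices).

**geNorm.** M values use the sample (n−1) standard deviation of pairwise
log2 ratios, log base 2 throughout, matching the original spreadsheet
convention so results are comparable with qBase output. Stepwise exclusion
removes the highest-M gene and recomputes; ties are broken by excluding the
alphabetically later identifier, making runs deterministic. The last two
genes share the top rank and a single M. V(n/n+1) compares geometric-mean
normalization factors of the n and n+1 best genes; the smallest n with
V < 0.15 is recommended, and when no V clears the cutoff the fall-back is
all G genes, with a warning — mirroring the situation where a three-gene
panel with V(2/3) above the cutoff leads to using all three. M < 0.5
(strict) flags a gene as stable; CV is sd/mean of NF-normalized quantities
on the linear scale.

## What the simulator emulates — and what it does not

`simulate_counts()` mimics the discovery design: one sequencing library per
stress/control pair across several conditions, base expression log-uniform
between 500 and 375,000 reads (the observed span of real candidate miRNAs),
per-sample library factors log-uniform in [0.5, 2], and multiplicative
gamma noise with variance = `dispersion` (default 4e-4, i.e. 2% CV — the
technical reproducibility the qPCR validation is matched to). The gamma
mean–dispersion form is negative-binomial-like but collapses to the exact
rounded mean as dispersion → 0, which gives clean noiseless round-trip
tests. Planted unstable miRNAs receive per-condition log2 effects drawn
from N(0, 0.5) and *centered across miRNAs within each condition*: under
per-library normalization a global mean log2 shift is indistinguishable
from a library-size factor (which the generator parameterizes separately),
so only centered effects are identifiable as fold changes — uncentered
truth would make "recovering the planted effect" ill-posed, not harder.

`simulate_cq_panel()` inverts the quantification model
(`Cq = intercept − log_(1+E/100)(q)` plus Gaussian technical noise, default
3 technical replicates for each of 3 biological samples per condition), and
`simulate_dilution_series()` inverts the efficiency fit, so zero-noise
simulations are exact fixed points of the pipeline — the basis of the
machine-precision round-trip tests.

Real data differ in ways the generator does not model: sequencing noise is
count-based (Poisson at low depth, where 2% CV is unattainable), miRNA
families cross-hybridize, amplification can be inhibited sample-specifically,
and real stress responses need not be mean-centered. Passing the planted
recovery tests therefore demonstrates the *inference machinery* is correct
under its stated model, not that 7%/500 are optimal thresholds for any
particular experiment.

## Problem sizes used in the checks

The oracle-equivalence suite compares the stepwise implementation against a
naive brute-force re-derivation on 500 random matrices up to 7 genes × 10
samples (tolerance 1e−10). Planted-truth recovery uses the study-shaped
default configuration — 200 miRNAs, 30% stable, 2% CV — over 200 seeded
runs for the count filter (sensitivity ≥ 0.95) and 200 seeded 8-gene × 6
sample panels for the ranking separation. These sizes give stable pass/fail
behaviour while keeping the default test run fast.

## Numerical notes and limitations

* Everything is plain double precision; no quantities are ever logged at
  zero because validation rejects nonpositive quantities up front.
* The count normalization target is the *mean* raw library size, so
  rescaling one library rescales the whole normalized matrix by a common
  factor; all downstream statistics (residuals, filters, geNorm) are
  unaffected, but normalized read values are comparable only within a run.
* With only two candidate genes geNorm degenerates: both share one M and no
  V series exists; `genorm()` reports the pair and recommends both.
* The stability filter flags low variation, it does not test significance;
  with one library per condition there is no replication to test against.
* NormFinder- and BestKeeper-style model-based rankings are out of scope.
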