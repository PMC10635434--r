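---
title: "Models and methods behind ploidyshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ploidyshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyshift)
```

## What the package models

ploidyshift analyses a recurring outcome of adaptive laboratory evolution
(ALE) in diploid-founded yeast populations selected on maltose: the
emergence of haploids carrying an extra copy of the chromosome bearing a
focal α-glucoside transporter gene, and the dissection of *why* those
karyotypes win. Five analysis stages are covered, each fed either by real
tabular data or by the package's own generators:

1. **Karyotype from windowed depth.** Relative chromosome copy number,
   integer aneuploidy calls in clones, and population aneuploidy-frequency
   trajectories.
2. **Ploidy from DNA-content cytometry.** A constrained 1C/2C/4C Gaussian
   mixture yielding the haploid fraction of a population, plus clone
   classification against controls, colony-genotyping proportions, and
   exact binomial allele-balance tests.
3. **Fitness from competition assays.** Selection coefficients by ln-ratio
   regression, Mann–Whitney group comparisons, and a factorial
   decomposition of fitness into ploidy, mating-type, and cell-type
   effects.
4. **Aneuploid gene expression.** Median-of-ratios normalisation, fold
   changes, an in-package Benjamini–Hochberg filter, two dosage null
   models for a focal gene, gene-class attenuation comparisons,
   subtelomere flags, percentile ranks, and ΔΔCt.
5. **Promoter motifs and reporters.** IUPAC consensus scanning on both
   strands, site ablation by point mutation, and Welch comparisons of
   reporter fluorescence.

## The synthetic world

The generators state one fixed world; their defaults are not tuning knobs.

* **Depth** is negative binomial per 1-kb window with size 20 (moderate
  overdispersion; windowed short-read depth is noisier than Poisson). The
  expected relative coverage of chromosome `c` in a population with
  haploid fraction `h` and extra-copy cell frequency `a_c` is
  `(P + a_c)/P` with `P = h + 2(1 − h)` genome equivalents per cell.
* **Cytometry** draws each cell from a Gaussian at `μ·k`, `k ∈ {1,2,4}`,
  with a shared CV of 0.08. Mixing weights come from `h` and a G1 fraction
  `α` shared between ploidies: haploid G2 cells and diploid G1 cells both
  sit in the 2C peak. Debris and doublets are not simulated, so a green
  recovery test says nothing about gating robustness.
* **Competition** follows `ln r(t) = ln r(0) + s·g(t)` with binomial
  sampling of 13,000 cells per time point; `log2(10) ≈ 3.32` generations
  per transfer in the ALE regime and `log2(100) ≈ 6.64` in rich medium,
  matching the two dilution schemes.
* **Expression** is negative binomial with size 100 (dispersion 0.01,
  typical for deeply sequenced biological-triplicate yeast RNA-seq) around
  `baseline · dosage^attenuation · induction · cis-boost`. The attenuation
  exponent defaults to `log2(1.58) ≈ 0.66`, so a doubled chromosome yields
  a median fold change of 1.58 — the calibration the analysis is designed
  to detect. The focal transporter is the stated exception: it responds
  with **full** dosage and, in haploid-like samples in maltose only,
  an additional cis boost of 1.69 on top of its 2.3-fold maltose
  induction. Making the boost maltose-specific is what lets the two null
  models agree in glucose (excess ≈ 0) and disagree in maltose (excess ≈
  0.69); making the focal gene escape attenuation is what makes the
  copy-number null (a plain 2-fold multiplier) the correct reference for
  that excess.
* **Colony genotyping** is multinomial, with haploids assigned MATa with
  probability 1 by default; the mating-type skew is exposed as a parameter
  because its mechanism is not asserted.

Randomness flows through named sub-streams derived from one master seed
(`substream_seed()`), so adding one generator call never perturbs another
— the property the round-trip and determinism tests rely on.

## Numerical choices worth knowing

**Median normalisation and its quantisation.** `relative_copy_number()`
divides each chromosome's median window depth by the genome-wide median.
Medians of integer counts move in steps of one read, so single-run
`r_c` values jitter by roughly `1/depth_mean`; population-frequency
accuracy is therefore judged on means over replicate simulations. At high
population aneuploidy frequency the aneuploid chromosome's own windows
drag the genome-wide median up by a percent or two; the leave-one-out
baseline (`exclude_self = TRUE`) removes this and is the convention used
for frequency trajectories, while the plain genome-wide median remains the
default for clone karyotyping.

**Mixture identifiability.** The 1C/2C/4C weight map is symmetric in
`(h, α)`; the swap is resolved by picking the orientation whose G1
fraction is nearer `alpha_hint` (0.6 for asynchronous cultures). More
fundamentally, a sample with only two occupied peaks fits equally well as
`(μ, h = 0)` and `(2μ, h = 1)` — the reason DNA-content experiments always
run known-ploidy controls. `estimate_1c_peak()` extracts the
swap-invariant G1 peak from a control, and `mu_bounds` anchors the sample
fit to it. The likelihood is maximised by multi-start quasi-Newton ascent
on transformed parameters rather than EM: the tied means (μ, 2μ, 4μ) and
shared CV leave no closed-form M-step, and a binned likelihood (512 bins)
makes each fit take well under a second at n = 10,000.

**Selection coefficients.** Ordinary least squares on `ln(query/competitor)`
versus cumulative generations, zero-count time points dropped rather than
pseudo-counted (pseudo-counts bias the slope). The t-based CI is slightly
anticonservative (~94% coverage) when the query saturates late in the
assay; assays for strongly selected queries should start them below parity,
as the original protocol's ratio adjustments do.

**Variance partitioning.** `decompose_effects()` reports both type II and
sequential (type I, cell type first) sums of squares. In the 8-genotype
panel, cell type and collapsed mating type are correlated (only the
heterozygous MAT configuration is diploid-like), so the two partitions
differ materially: the headline "cell type explains ~0.93 of the sum of
squares" is the sequential number; the order-free type II attribution is
~0.6 with the remainder shared. Both are printed so the reader can see the
difference rather than trust a default.

**Exact small-sample tests.** The Mann–Whitney p-value uses the exact null
distribution for combined n ≤ 25 without ties (normal approximation with
tie and continuity corrections otherwise), and the allele-balance test
sums all binomial outcomes no more probable than the observation. Both are
checked against brute-force enumeration, as are the BH step-up, the
median-of-ratios size factors (also against DESeq2's implementation), the
motif scanner (against a per-position naive scan), and percentile ranks.

**Motif ablation.** Sites are destroyed by transversion of every position
(A↔C, G↔T); the variant is re-scanned and the operation errors if the
consensus still matches — which can only happen when the consensus
contains N positions, since N matches any base. An N in the *sequence*
never matches, so masked bases cannot create hits.

## Design decisions that were genuinely open

* Window size (1 kb), the minimum-contig filter (100 kb), and the ±0.25
  rounding tolerance for integer calls are defaults the data do not
  dictate; all are arguments.
* Colony-genotyping estimates are reported as-is but documented as
  conservative lower bounds on haploid frequency, since homothallic mating
  before genotyping can only convert haploids into diploids.
* The built-in per-gene Welch test on log-normalised counts is labelled a
  screening device, not a substitute for a negative-binomial DE framework;
  externally computed p-values are accepted everywhere p-values are used.
* The dosage-null "excess" averages the induction model and the
  copy-number model over evolved strains in maltose; per-strain and
  per-model values are returned so other averaging conventions are a
  one-liner.
* The published 69% excess is compressed to ~64–66% in the synthetic
  recovery because size factors computed over all genes absorb one or two
  percent of the aneuploid chromosome's signal — a property real
  median-of-ratios analyses share.

## What a green test establishes — and what it does not

The recovery tests show that the estimators invert the generators at
realistic noise levels: selection coefficients to ±0.005 with 13,000-cell
sampling, haploid fractions to RMSE < 0.06 across the full mixing range,
integer karyotypes exactly at 20× depth, the cis boost to ±0.05 over 20
simulated studies. They do not validate read mapping, gating, GC or
mappability artefacts in depth, S-phase cells between cytometry peaks, or
negative-binomial DE testing — all out of scope, with the first three
absent from the generators by construction.
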