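---
title: "Integrating SNP-array copy number with gene-expression deregulation"
author: "cndosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating SNP-array copy number with gene-expression deregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cndosage)
```

## The analysis model

`cndosage` integrates two genome-wide measurements made on a small panel of
tumour cell lines: discrete copy-number (CN) states per SNP probe from an
SNP array, and normalized expression intensities from an expression array,
contrasted against a set of normal-tissue controls.  The question the
toolkit addresses is how much of the expression deregulation observed in
the tumour lines is attributable to gene dosage, and where dosage fails to
explain it — repressed amplified genes, discontinuously altered segments,
and spatial clustering of deregulated genes.

The pipeline is a chain of simple, explicit constructions:

1. **CNAs.** Each sample's per-SNP states (0 homozygous deletion, 1
   heterozygous deletion, 2 diploid, 3 single-copy gain, 4 amplification)
   are collapsed to gain / loss / normal, and every maximal run of
   consecutive same-direction altered SNPs becomes one copy-number-altered
   region.  An isolated altered SNP is a single-SNP CNA.  The region span
   is the position of the first to the last member SNP — no extension
   toward the flanking normal probes, so spans are conservative.
2. **MRRs.** Minimal recurrent regions are the n-way interval intersection
   of the per-sample CNA sets: maximal intervals carried by at least one
   CNA of *every* sample.  Direction need not agree across samples; a
   region gained in some lines and deleted in others is labelled
   `combined`.  Intervals holding no probe are dropped, and by default an
   MRR must contain at least one recurrent SNP (a SNP altered in all
   samples); both knobs are exposed in `find_mrrs()`.
3. **Gene dosage.** A gene is CN-altered in a sample when its span
   intersects any CNA of the sample (any overlap, not containment), and
   the altered SNPs falling inside the span are counted separately:
   a gene can be "inside" a CNA while owning zero altered SNPs, which is
   exactly the situation the discontinuity analyses exploit.
4. **Deregulation calls.** Genes are called up/down/unchanged from fold
   change (tumour mean over control mean of the raw intensities) plus a
   moderated two-class statistic d = (mean difference)/(s + s0) computed on
   log2 intensities, with label-permutation estimation of the false
   discovery rate.  A gene is `up` only when the fold change reaches the
   cutoff *and* the permutation procedure calls it at the chosen threshold
   with acceptable local FDR.
5. **Regional statistics.** Arm/cytoband enrichment of altered SNPs or
   deregulated genes uses the Yates-corrected 2x2 chi-square with an
   automatic Fisher fallback; gene-set enrichment uses the parametric
   Z = (Sm − μ)·√m / δ with μ, δ taken from all deregulated genes; trend
   analyses use the linear-by-linear association M² = (N−1)r² and Spearman
   correlations; clustering of contiguous deregulated genes is tested
   against a Monte-Carlo permutation null.

## Parameters that matter

* `de_config()` — fold-change cutoffs default to 1.5 and 1/1.5 (the
  down cutoff is stored at full precision; 0.66 is its display rounding),
  target global FDR 0%, local FDR < 10%, s0 = median of the per-gene
  standard errors, 200 permutations.  These mirror common microarray
  practice for small designs (triplicate tumours vs ~10 controls).
* `find_mrrs()` — `min_samples` defaults to "all samples"; lowering it
  relaxes recurrence.  `require_recurrent_snp` defaults to TRUE.
* `two_by_two_chisq()` — the Yates continuity correction is ON by default;
  with the cell-line-scale counts this package targets, the corrected
  statistic is the one that reproduces published contrasts of this design.
* `mrr_deregulation_test()` — the background *includes* the tested region
  by default (each region is compared against the whole region set, the
  convention used in the source analyses); `include_self = FALSE` gives
  the sharper leave-one-out contrast.
* `page_scan()` — fold changes enter on the signed log2 scale so up- and
  down-sets are symmetric; `scale = "ratio"` switches to raw ratios.
  Sets with fewer than 10 deregulated genes are reported but not scored.
* Trend binning — region-level bins default to 1–100 / 101–500 / >500
  SNPs; gene-level binning should include a 0-SNP bin because most
  CN-altered genes lie between two altered SNPs and own none.

## What the synthetic generator emulates

`sim_config()` encodes the study conditions as defaults: 4 tumour samples,
~23.6 kb mean inter-SNP spacing (a homogeneous Poisson process — the real
array map is heterogeneous, which we do not emulate), triplicate tumour
expression profiles against 10 controls, an explored-gene fraction of 0.63
(the share of genes represented on the expression platform), and a gain
fraction of 0.55 among planted regions with amplification (state 4) at 11%
of gained SNPs and homozygous deletion at 1% of lost SNPs, matching the
published composition of altered SNPs.  The desk-scale genome is 4
chromosomes of 50 Mb with 1,200 genes — the same probe and gene densities
as the genome-wide data at 1/15 of its size; gene spans are lognormal
(median 30 kb) so the altered-SNPs-per-gene distribution is skewed with
most genes carrying 0–3 SNPs, as observed.

The expression model couples deregulation to the planted copy number
through an explicit dose-response: the probability that an in-region gene
is *truly* altered is 1 in a fully continuous region and k/(k+3) in a
discontinuous one, where k is the altered-SNP count in the gene span.  The
concordant response (up for gains, down for losses) is `dosage_up_prob`
times that weight; gained genes additionally acquire a repressed fraction
(`repression_prob`) and a partial-silencing term that grows linearly with
k (`partial_silencing_slope`), which is the mechanism behind the
downregulation trend the trend statistics recover.  An AR(1) Gaussian
copula along the gene order (`cluster_rho`) makes deregulation spatially
clustered without changing marginal rates.

What passing tests on this generator do **not** show about real data: no
probe-level artifacts, GC waves, subclonality, or platform-specific
normalization effects are simulated, the inter-SNP spacing is homogeneous,
and baseline intensities are independent across genes apart from the
planted spatial correlation.  Recovery results are therefore statements
about the algorithms, not about array chemistry.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed everywhere inside the package; only BED
  I/O and UCSC cytoband input convert (0-based half-open).  Band-boundary
  ties go to the lower-coordinate band.
* CNA runs break at direction changes, so every region has a single
  direction label; states 3/4 and 0/1 are merged for run construction and
  kept separate only in composition summaries.
* The accounting table computes average-row percentages as ratios of
  unrounded mean counts, and rounds only at report time.
* The permutation FDR uses the median false-call count; with target 0%
  the chosen threshold is the smallest with zero median false calls, and
  when no threshold reaches the target the closest one is returned with a
  warning.  The local FDR is a windowed ratio of expected-null to observed
  gene counts around each statistic (window 0.25 sd of d).
* Zero-variance location tests (all member log2 ratios equal) are flagged
  `degenerate` and reported with p = 1; single-region enrichment scans
  return NA; a PAGE background with zero spread is an error.
* The cluster randomness test falls back from the goodness-of-fit
  chi-square to the Monte-Carlo tail probability when an expected cell
  drops below 1, and is reproducible by seed.

## Design decisions taken where the design was open

* Whether an upstream segmenter would merge runs across direction changes
  is unknowable from state tracks alone; we require direction-homogeneous
  runs so each region carries one label.
* "Minimal" recurrent regions are the maximal common-intersection
  intervals; we do not split them further.
* Whether gene spans are transcript or locus extents is left to the
  annotation supplied by the user.
* The cluster test is formalized as a permutation-calibrated comparison of
  clustered vs unclustered deregulated counts, since "compared with a
  random distribution by chi-square" admits several readings; runs mixing
  up- and down-regulated genes count as clusters.
* All randomness flows from a single seed, split per stage, so a pipeline
  run is reproducible end to end.

## Problem sizes

The test suite and the acceptance script run the generator at the default
desk scale (≈8,500 probes, 1,200 genes, 22 expression samples) and use 100
label permutations for the FDR, 400–5,000 Monte-Carlo permutations for the
cluster test, and 10 seeds for the stochastic recovery properties; these
sizes were chosen so the full suite exercises every stage at the study's
densities while remaining convenient to run interactively.

## Known limitations

The SAM-style caller is a simplified two-class unpaired re-implementation
(s0 by quantile, windowed local FDR) rather than a wrap of any specific
software release, so genome-wide called counts from the original analyses
are not exactly reproducible — the printed contrasts and accounting
arithmetic are the reproducible contract.  MRR discovery has no background
model of recurrence (no GISTIC-style q-values); recurrence here is the
deterministic all-samples intersection.  The qPCR/FISH calculators assume
quantities interpolated upstream; no standard-curve fitting is performed.
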