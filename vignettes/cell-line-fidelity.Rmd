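---
title: "Grading renal cancer cell lines by genomic concordance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading renal cancer cell lines by genomic concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Renal cell carcinoma (RCC) is not one disease: clear cell (ccRCC),
papillary (pRCC) and chromophobe (chRCC) tumours carry distinct,
well-characterized arm-level copy-number signatures — 3p loss with 5q gain
and chromosome 14 loss in ccRCC; gains of chromosomes 7, 17, 16, 12 and 20
in pRCC; near-pan-monosomy of chromosomes 1, 2, 6, 10, 13 and 17 in chRCC.
Cell lines are routinely chosen as models of one of these subtypes, yet two
widely used cell-line resources frequently disagree about the same line's
mutations and copy-number calls, and some heavily cited lines do not
resemble the subtype they are assumed to model. `rccmatch` implements a
pipeline for asking, quantitatively: *which subtype does a cell line's
genome actually match, and how consistently do independent data sources
describe it?*

The pipeline has six analysis stages, each usable on its own:

1. **Harmonization** — segmented log2-ratio profiles and allele-specific
   integral copy numbers (PICNIC-style total/minor pairs) are reduced to a
   common representation. Integral calls are converted to log2 ratios by
   dividing each segment's total copy number by the sample's
   length-weighted average copy number and taking log2, so each profile is
   relative to its own ploidy. Mutations pass a confidence filter
   (depth ≥ 15 reads, variant allele fraction ≥ 15%, non-coding and silent
   classes excluded).
2. **Similarity** — Jaccard index on binary mutation profiles; Pearson or
   Spearman correlation on gene-level copy number or expression, with
   pairwise missing-value exclusion; matched pairs are compared against the
   unmatched background by within-row rank.
3. **Copy-number statistics** — fraction genome altered
   (FGA = Σ L(i)·1[|CN(i)| ≥ T] / Σ L(i), T = 0.2) and the fraction of an
   arm lost (value ≤ −0.2), both length-weighted with inclusive
   thresholds; plus two allele-specific estimators of arm loss (below).
4. **Co-clustering** — tumours and cell lines clustered together on
   gene-level copy number with distance 1 − Spearman ρ and average
   linkage; the dendrogram is cut at height 0.9 and each cell line
   inherits the majority tumour subtype of its cluster (clusters with
   fewer than 5 tumours, or tied majorities, yield "outlier").
5. **Concordance tiers** — for each gene and cell line shared by two
   sources: Tier 1 = identical calls, Tier 2 = same gene / same direction
   but different variant or extent, Tier 3 = present in one source only or
   opposite directions. Lines are ranked by their count of discordant
   calls; a line with no Tier 2/3 calls has every reported alteration
   confirmed by two independent sources.
6. **Aggressiveness** — tumours co-clustering with cell lines are compared
   with the rest (stage, grade, FGA, per-gene mutation frequency; Fisher's
   exact tests), with a quartile-of-mean-correlation variant that avoids
   dependence on any single dendrogram cut.

A seeded synthetic-cohort generator reproduces the statistical structure
each stage assumes, so the whole pipeline is testable offline.

## Why two estimators of 3p loss

Total-copy log2 ratios can hide a real loss twice over:

* **Masked loss** — the minor allele is fully lost (copy number 0) while
  the major allele is amplified, leaving the *total* copy number at or
  above the sample average. The log2 estimator sees nothing; the
  minor-allele estimator (`arm_loh_fraction`, fraction of the arm with
  minor copy number 0) sees a complete loss.
* **Ploidy-relative loss** — an arm sits at absolute total copy number 2
  in a genome whose average copy number is, say, 3.2. Relative to the
  sample's ploidy the arm is lost. We call a segment relatively lost when
  its total copy number is at least 0.5 below the sample's length-weighted
  mean; 0.5 separates adjacent integer states around a fractional mean
  (the margin is configurable).

The combined call uses an either-method rule with an 80% cutoff: an arm is
`lost` if either available fraction reaches 0.8, `negligible` if all
available fractions are below it, `indeterminate` if neither estimator
could be computed. Denominators always use covered (clipped-to-arm)
length: uncovered genome carries no evidence, so it neither supports nor
refutes a loss.

## The expression classifier

The ccA/ccB prognostic subtypes of ccRCC are called by a nearest
shrunken centroid model. With class centroids $\bar x_{kj}$, overall
centroid $\bar x_j$, pooled within-class standard deviation $s_j$, fudge
constant $s_0 = \mathrm{median}_j(s_j)$ and normalizer
$m_k = \sqrt{1/n_k - 1/n}$ (the exact standard error of a class centroid
minus the grand mean under equal variance; the $\sqrt{1/n_k + 1/n}$
variant used by some implementations is available via `m_formula`):

$$d_{kj} = \frac{\bar x_{kj} - \bar x_j}{m_k (s_j + s_0)}, \qquad
  d'_{kj} = \mathrm{sign}(d_{kj})(|d_{kj}| - \Delta)_+, \qquad
  \bar x'_{kj} = \bar x_j + m_k (s_j + s_0)\, d'_{kj}.$$

The threshold $\Delta$ is chosen by seeded, class-stratified 10-fold
cross-validation, minimizing mean per-class error with ties broken toward
larger $\Delta$ (fewer genes). New samples are called by Spearman
correlation with each class's shrunken centroid over the surviving genes:
a sample is assigned the class whose correlation exceeds the other's by at
least 0.05 (inclusive), otherwise it is left unclassified. Correlating
against shrunken centroids is the default because classification is
defined on the post-shrinkage gene set; raw class means are available via
`use_shrunken = FALSE`. Class priors are uniform; they matter only in the
degenerate case where no gene survives shrinkage.

### Batch correction

Expression sources are merged after a parametric empirical-Bayes batch
adjustment: each gene is standardized, per-batch location and scale
effects are estimated, shrunk toward batch-level priors (normal for
locations, inverse-gamma for scales, method-of-moments hyperparameters,
conditional estimates iterated to tolerance 1e-6) and the data
back-transformed. One deliberate design choice departs from the common
reference implementation: **location effects are removed exactly** in the
adjusted data, while the empirical-Bayes *shrunken* location estimates are
reported in the fitted model and the scale correction uses its shrunken
estimates. Rationale: shrinking the subtracted location term leaves a
residual between-batch mean difference of order
$\delta/(n\tau^2+\delta)\cdot(\hat\gamma - \bar\gamma)$ per gene, which
re-introduces exactly the artefact the correction exists to remove;
equal post-correction batch means is the contract downstream stages (and
our acceptance checks) rely on. Scale estimates use the 1/n
(maximum-likelihood) variance so that correcting a batch that is an exact
copy of another, up to a location shift, is an exact identity. Genes with
zero pooled variance are left unadjusted with a warning; a single batch is
an identity transform with a warning.

## The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated against cohorts whose ground truth is known exactly.

* **Genome** — 22 chromosomes at ~1/1000 real lengths, 25 genes per arm
  (~1,100 genes). This preserves arm semantics ("fraction of 3p") while
  keeping per-base-pair oracle checks affordable.
* **Archetypes** — each subtype is a list of (arm/chromosome, direction,
  penetrance, magnitude) events plus focal events (Poisson count,
  exponential length) and per-gene mutation rates. Default penetrances
  follow published karyotype frequencies (e.g. ccRCC: 3p loss 0.9, 5q gain
  0.7, 14 loss 0.5, 8q gain / 6q loss / 9p loss 0.35, 1p loss 0.25). The
  ±0.5 log2 arm magnitude and per-segment noise sd 0.1 are calibration
  choices — the literature reports event frequencies, not log2 effect
  sizes on any particular platform.
* **Segmentation granularity** — noise is Gaussian per *segment*, and each
  arm is pre-divided into 5 baseline segments. Real array segmentations
  produce tens to hundreds of segments per profile; modelling whole arms
  as single noise units would give inter-sample rank correlations a
  spurious ±0.15 component (only ~44 independent units per genome), which
  no real profile pair exhibits.
* **Cell-line burden** — cell lines double the penetrance of their
  archetype's secondary events (capped at 1) and double the focal rate,
  so their FGA distribution stochastically dominates the tumours' without
  tuning to any particular median.
* **Two-source views** — paired copies of the truth with seeded injected
  discrepancies: `drop` (one-sided call, → Tier 3), `alter` (perturbed
  protein change, → Tier 2), `extent_shift` (±2 ↔ ±1 score, → Tier 2).
  Every injection is recorded in a ledger with its expected tier, so
  recovery is checked count-exactly.
* **Expression** — per-gene baselines ~ N(7, 3²) log2 units, a two-class
  effect confined to marker genes (half up in ccA, half down),
  intermediates at the midpoint, per-batch location/scale effects on top.
  The heterogeneous baselines matter: they are what makes every sample
  correlate highly with *both* class centroids (as observed in real
  expression data) and makes the 0.05 correlation margin a meaningful
  discriminator; with flat baselines the margin rule would behave
  completely differently.
* **Clinical covariates** — stage and grade are drawn with advanced
  disease probability increasing in FGA through a logistic link, centred
  at the cohort mean.
* **Determinism** — every sample draws from its own RNG stream derived by
  hashing (sample id, seed), so outputs are invariant to group ordering.

What the generator does **not** emulate: tumour purity and subclonality,
germline contamination, sequence-level reads, platform-specific probe
noise, and correlated event co-occurrence beyond the archetype's
independent Bernoulli draws. Passing tests on synthetic cohorts therefore
demonstrate that the estimators and decision rules are implemented
correctly and behave as designed under the stated statistical structure —
not that they would recover truth on any particular real dataset.

## Numerical choices

* All alteration thresholds are inclusive (|CN| ≥ T, value ≤ −0.2,
  correlation margin ≥ 0.05), applied identically in FGA, arm loss and
  GISTIC-like discretization.
* GISTIC-like discretization (±0.2 shallow, ±1.0 deep) is for synthetic
  log2 matrices only; externally supplied integer scores pass through
  untouched.
* Jaccard of two empty sets is 0 with a `both_empty` flag — an all-empty
  pair carries no evidence of similarity.
* Correlation cells with fewer than 3 shared non-missing features, or a
  zero-variance vector, are flagged missing rather than propagating NaN.
* Agglomeration is `stats::hclust` average linkage, deterministic for a
  fixed input order; cutting keeps merges at exactly the cut height.
* Zero-copy segments map to log2 = −8 (configurable floor) with a warning.
* Variant identity for the tier scheme is equality of (normalized
  protein-change, variant class): case and whitespace folded, `p.` prefix
  stripped. Multi-variant genes are compared as sets; any both-sided
  difference is Tier 2. Silent agreement (both sources report nothing) is
  `concordant_null`, excluded from Tier 1 counts so that "perfect
  agreement" statements refer to confirmed *alterations*.
* Quartile splits take floor(n/4) samples from each end with stable-order
  tie handling, flagged when ties exist. Per-gene Fisher p-values are
  reported unadjusted for multiplicity (and labelled as such), mirroring
  per-gene reporting practice.
* Fisher's exact test is the two-sided summation of hypergeometric
  probabilities ≤ that of the observed table, with the conditional
  maximum-likelihood odds ratio (via `stats::fisher.test`); tables with a
  zero margin return p = 1 with a flag.

## Problem sizes and observed behaviour

The test suite and acceptance script run entirely on synthetic data at
these scales, chosen to exercise the study-scale structure while staying
fast: 100 tumours per subtype plus 10 cell lines per subtype for
clustering (330 samples × ~1,100 genes); 100 samples per expression class
plus 40 intermediates over 1,100 genes with 200 markers; 500 random
profiles for the per-base-pair oracle comparisons; all ~132,000 2×2
tables with total count ≤ 40 for the Fisher oracle.

At these defaults the dendrogram cut at 0.9 recovers the three subtypes
with an adjusted Rand index typically between 0.89 and 0.95 across seeds
(the residual disagreement comes from near-euploid tumours that drew few
archetype events and cut off as singletons — the synthetic counterpart of
real outlier clusters); all ccRCC-archetype cell lines are called
ccRCC-like and no pRCC-archetype line ever is. The masked-loss scenario
yields a minor-allele 3p loss fraction of 1.0 against a log2 fraction of
0.0. The expression classifier reaches ~100% held-out accuracy with
essentially all intermediates unclassified under the 0.05 margin.

## Limitations

* The tier scheme adjudicates agreement, not correctness: a concordant
  pair of sources can agree on a wrong call.
* The relative-loss margin (0.5 copies below the sample mean) is a
  design choice; profiles with extensive subclonality would need a
  purity-aware margin.
* The co-clustering split depends on one dendrogram cut; the quartile
  variant is provided precisely because of that sensitivity.
* The classifier is two-class by construction; it reports `unclassified`
  rather than extrapolating to unseen subtypes.
* External-resource adapters read local copies of the published file
  formats; no download tooling is included.
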