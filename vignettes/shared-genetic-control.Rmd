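---
title: "Methods: separating cell-composition confounding from shared genetic control"
author: "emcovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating cell-composition confounding from shared genetic control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emcovar)
```

## The problem

Whole-blood gene expression and DNA methylation are both strongly
cell-type specific, and the cellular composition of blood varies between
individuals. When the two data types are profiled on the same people, an
exhaustive search for expression–methylation correlations therefore returns
an enormous number of significant pairs whose common cause is differential
cell counts, not a regulatory or genetic link. This package implements a
complete pipeline for (i) running that exhaustive search with honest
asymptotic inference, (ii) diagnosing and removing the cell-composition
signal, and (iii) establishing shared genetic control for the pairs that
survive, via shared QTLs and bivariate genetic correlations.

## Correlation inference

For each expression probe × methylation probe pair, the Pearson correlation
is computed over the pairwise-complete individuals and converted to a
two-sided p-value through the Fisher Z transform: under bivariate
normality, `atanh(r)` is approximately `N(atanh(ρ), 1/(n−3))`, so
`p = 2 Φ̄(|atanh(r)| √(n−3))`. Choices:

* **Two-sided tests** throughout (H1: ρ ≠ 0).
* **`1/(n−3)` variance.** The alternative `1/n` convention changes the
  n = 610 significance boundary only in the third decimal; `1/(n−3)` is the
  standard small-sample correction and reproduces the printed boundary
  |r| = 0.27 at the family-wise cutoff.
* **Log-space evaluation** of the tail so p-values near 10⁻¹² and far below
  do not underflow; `p = 0` is emitted only for `|r| = 1`, with a warning.
* **Pairwise-complete n**, with a floor of `min_n = 10` (dropped pairs are
  tallied, never silently discarded); below ~10 observations the asymptotic
  p-value is not meaningful. No floor is inherent to the method, so the
  value is exposed.
* **Bonferroni control only** — the analysis controls the family-wise error
  over all `n_expr × n_meth` tests at α = 0.05; no FDR variant is offered.

`cross_correlate()` evaluates the full cross-correlation in blocks of probe
indices: per block it forms the six masked cross-products needed for
pairwise-complete moments, so memory is bounded by the block size while
every pair's statistics are computed from identical full-length dot
products. The emitted pair set is therefore bit-identical for every block
partition — a property the tests assert against a dense oracle. An
out-of-core memory-mapped backend was considered and rejected: at the
problem sizes this package targets the matrices fit comfortably in memory,
and the block loop alone already provides the memory bound; a file-backed
store would add an I/O layer without changing the algorithm.

Probe pair distances use probe midpoints (the anchor choice is not
material at the 0.5–1 Mb windows used); a pair is *cis* when the midpoint
distance is at most the window, with a closed boundary (distance equal to
the window counts as cis).

## The correlation graph as a confounding diagnostic

Significant pairs with |r| ≥ 0.5 define a bipartite graph. Connected
components are computed (igraph) and labelled deterministically — ordered
by size, ties broken by the smallest member id — so reports diff cleanly;
the labelling is checked against an independent breadth-first-search oracle.
Cell-composition confounding produces large components; their probes should
separate purified blood-cell reference samples by cell identity. That
visual claim is operationalized as a score: average-linkage hierarchical
clustering of reference samples on Euclidean distance restricted to the
component's probes, cut at the number of cell types, compared with the true
identities by the adjusted Rand index (1 = perfect recovery, 0 = chance). A
permutation null (label shuffling) is available to calibrate "no relation".
Average linkage and Euclidean distance are defaults chosen for robustness;
methylation is clustered on the β scale, where the purified-cell reference
data live. The score, not the dendrogram, is the package's quantitative
stand-in for the clustering figure.

## Cell proportions: observed, predicted, calibrated

Observed proportions are cell counts divided by the per-individual total
over the eight counted types. The predictor is a re-trained
reference-based deconvolution:

1. Rank every methylation probe per cell type by a one-vs-rest two-sample
   t statistic with the per-probe pooled variance shrunk toward the
   across-probe mean (`s²* = (d₀ s̄² + d s²)/(d₀ + d)`, prior weight
   `d₀ = 4` pseudo-samples, configurable; `d₀ = 0` recovers the plain
   pooled t). The moderation is implemented in-house so the pipeline has no
   annotation-package dependencies; it is cross-checked against both a
   plain-t oracle and limma's moderated t in the tests.
2. Take the union of the top-k probes per cell type (k = 70 by default),
   intersect with the probes present in the target dataset, and store each
   selected probe's mean reference β per cell type.
3. Regress each individual's raw β values over the selected probes on the
   reference columns by OLS — **no intercept, no constraints**: predicted
   proportions may be negative and need not sum to one, because the
   reference panel does not cover all nucleated cells (deliberately, only 7
   of the 8 simulated types have reference profiles — no basophil — so the
   missing type acts as unmodeled noise, as in real reference panels).
4. Calibrate per cell type by the affine map that makes the regression of
   predicted on observed values have slope one and intercept zero on the
   overlap. Calibration is per cell type (the types have very different
   scales); being affine, it cannot change rank correlations.

Adjustment takes residuals of each probe on the proportion columns plus an
intercept. Observed proportions sum to one, which is collinear with the
intercept: the largest-mean cell-type column is dropped, with a warning —
the fitted subspace, hence the residuals, are unchanged by which column
goes. The deconvolution regression excludes the intercept (projection onto
reference profiles); the adjustment regression includes it (centering):
each matches its method's standard formulation.

### How much confounding survives an imperfect predictor?

Under a linear single-confounder model — two traits loading on a common
proportion `c`, adjusted by residualizing on a predictor `ĉ` with
`cor(ĉ, c) = r_pred` — the confounder-driven covariance is attenuated by
exactly `1 − r_pred²`: 44% of the original correlation remains at
`r_pred = 0.75`, 10% at `0.95`. The package states the remaining fraction
on the original trait scale (the ratio of covariances). Re-standardizing by
the shrunken residual variances gives the same number only in the
weak-loading limit; measured as a covariance ratio the identity is exact
for all loadings, which is also what makes the Monte-Carlo check sharp —
`simulate_residual_confounding()` averages the ratio over replicate trait
pairs at n = 100,000 and agrees with the closed form to within one
percentage point.

## Synthetic cohorts

The generator (`simulate_pedigree()` → `simulate_genotypes()` →
`simulate_cell_proportions()` → `simulate_trait_matrices()`) emulates a
twin-family blood cohort:

* **Pedigree**: nuclear families of two parents, one MZ or DZ twin pair
  (MZ probability 0.5) and 0–2 extra siblings (mean 1.2), so 117 families
  average ≈610 individuals — the structure of the classical twin cohorts
  this design mirrors.
* **Genotypes**: founders drawn in Hardy–Weinberg equilibrium at uniform
  MAFs in [0.05, 0.5]; offspring receive one allele per parent by an
  independent Mendelian draw per SNP (gene dropping); MZ twins are copies.
  There is **no linkage disequilibrium** by default — LD matters only for
  the multiplicity of shared associated SNPs, which the analysis reports as
  raw, LD-dependent counts anyway.
* **Cell proportions**: Dirichlet around a neutrophil-dominant base profile
  (Neu 0.55, CD4T 0.15, CD8T 0.08, Mono 0.07, B 0.06, NK 0.05, Eos 0.03,
  Baso 0.01) with concentration 40, giving a neutrophil-proportion SD of
  ≈0.08 — typical healthy-adult variability.
* **Traits**: each probe is a scaled sum of a cell-composition term (a
  single dominant cell type, signed), a genetic term (a planted cis QTL
  explaining 40% of variance plus an independent polygenic part up to
  h² = 0.6 for shared-QTL pairs), a shared latent "inflammation-like"
  factor, and Gaussian noise. Components are rescaled empirically so the
  realized variance fractions match the declaration; the true genetic
  values are stored for post-hoc evaluation. Methylation is generated on
  the M scale and emitted as β = 2^M/(1+2^M), exercising the β↔M round
  trip; marker probes are emitted directly on the β scale as
  proportion-weighted mixtures of purified-cell profiles so that
  deconvolution is actually identifiable from the cohort data.

Planted shared-QTL pairs share one causal SNP; their polygenic parts are
independent, so the implied true genetic correlation is
`±shared_qtl_var/shared_h2` (±2/3 at the defaults). Batch residualization
of the real data (batch, sex, age) is assumed already done — the generator
emits pre-residualized traits and does not model the logistic-link
residualization step used on raw arrays, whose exact residual definition is
ambiguous and upstream of everything this package tests.

What passing tests on these cohorts do **not** show about real data: there
is no LD, no measurement batch structure, no case–control composition
shift, cell loadings are single-type rather than graded, and the latent
factor is independent of genotype. The generator validates the machinery
and its calibration, not the biology of any particular cohort.

## QTL mapping and shared QTLs

Association is OLS of the (adjusted) trait on each SNP dosage, with
covariates projected out first; p-values from the t distribution with a
reporting floor of 10⁻³⁰⁰, and R² as the squared partial correlation.
Family structure inflates null OLS statistics; a two-step GLS mode is
provided (variance components by REML, then whitening by the fitted
covariance), and the tests verify it restores a genomic inflation factor
near 1 where plain OLS is inflated. Calibration-sensitive checks
(null-uniformity) run on unrelated individuals.

A pair shares a QTL when the intersection of its SNPs passing p < 10⁻⁵ in
both scans is non-empty; best SNPs are collected at the relaxed p < 10⁻¹
so every probe has a best SNP even without a genome-wide signal. Genomic
regions group sharing pairs by merging their probe-span intervals within
1 Mb (the merge distance is exposed — the notion of "region" is not
uniquely defined). SNP positions are 1-based internally; BED output is
0-based half-open, with the conversion confined to the writer.

## Variance components

The GRM is the standard allele-frequency-standardized estimator over SNPs
with MAF ≥ 0.01. As a Gram matrix it is positive semi-definite by
construction; eigenvalues below −10⁻⁸ (rounding) would be reported and
clipped. Univariate and bivariate models are fitted by average-information
REML with three initial EM steps and step-halving whenever a proposed
update is non-positive-definite or decreases the restricted likelihood;
convergence is declared when the log-likelihood changes by less than 10⁻⁶
(cap 100 iterations, both exposed). Traits are standardized to unit
variance, so components are variance fractions and `h² = V_A/(V_A+V_E)`.

The solver works in the GRM eigenbasis: with `V = G ⊗ K + R ⊗ I`, rotating
by the eigenvectors of K makes every REML quantity computable from n 2×2
blocks, so each iteration is O(n) after one eigendecomposition — which is
also shared across the probe pairs of a batch. Genetic and residual
covariance matrices are projected to the PSD cone after each update, which
constrains rG to [−1, 1]; when a genetic variance converges to the zero
boundary, rG is reported as `NA` with a `boundary` flag rather than an
unstable ratio. Standard errors come from the inverse AI matrix (delta
method for h² and rG). An optional common-family environmental component
(family-block covariance) is available for the univariate model through a
dense Cholesky path; it is off by default because the GRM built from
gene-dropped genotypes already carries the pedigree covariance.

A caveat the reports make visible: for pairs selected on high phenotypic
correlation, rG estimates in strata without genuine shared genetics are
boundary-inflated (small, noisy genetic variances in the denominator).
The stratified summaries are therefore means of |rG| by sharing status —
the contrast between strata, not the absolute level in the null strata, is
the interpretable quantity.

## Pipeline, determinism, problem sizes

`run_pipeline()` executes simulate → correlate → graph → adjust →
re-correlate → shared-QTL → rG, in that order, with every threshold in a
single serializable config whose hash covers exactly the semantically
meaningful fields. All randomness flows from one master seed through fixed
per-stage offsets, so a run is reproducible bit-for-bit from config + seed;
stage outputs checkpoint to disk and a rerun resumes transparently.
Filtered records (low-n pairs, zero-variance probes, monomorphic SNPs,
failed fits) are always tallied, never silently dropped.

The shipped test suite exercises the pipeline at deliberately desk-sized
settings — cohorts of 40–117 families (≈200–610 individuals), 600–2,000
SNPs, and a few hundred to a few thousand probes per platform; REML
parameter recovery uses 20 replicate cohorts at n ≈ 610 with 2,000 SNPs.
These sizes make every property checkable in minutes while keeping the
per-test Monte-Carlo error well inside the asserted tolerances; the
engine itself has no dependence on them.

## Known limitations

* No LD model, so shared-SNP counts on synthetic data are not comparable
  to LD-rich real panels (on real data they chiefly reflect local LD).
* OLS association is anticonservative under family structure; use the GLS
  mode, or founder-only subsets, when calibrated p-values matter.
* The deconvolution is unconstrained least squares; quadratic-programming
  variants with non-negativity are out of scope.
* Bivariate REML assumes complete, jointly observed trait pairs; pairs
  with heavy missingness fall back to per-pair eigendecompositions.
* Trans-chromosome pairs have no defined distance; they are classified,
  never assigned one.
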