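# emcovar

Quantifying shared genetic control of gene expression and DNA methylation
measured on the same blood samples.

When expression and methylation are profiled in whole blood, the dominant
source of correlation between an expression probe and a methylation probe is
usually not a regulatory link but the fact that both probes are specific to
particular blood cell types, and cell composition varies between
individuals. `emcovar` implements the full analysis needed to separate the
two: exhaustive pairwise correlation with asymptotic inference, a graph
diagnostic that exposes cell-composition confounding, reference-based
deconvolution and residual adjustment, shared-QTL detection, and bivariate
REML genetic correlations — plus a synthetic-data generator that emulates a
twin-family cohort with known ground truth, so every stage is testable
without any external data.

## The statistics at the core

**Fisher-Z correlation inference.** For a probe pair with Pearson
correlation *r* over *n* pairwise-complete individuals, `atanh(r)` is
asymptotically normal with variance `1/(n − 3)`, giving the two-sided
p-value `p = 2 Φ̄(|atanh(r)| √(n−3))`. With α = 0.05 Bonferroni-corrected
over all 16,659 × 303,078 expression–methylation tests the cutoff is
9.9 × 10⁻¹², which at n = 610 corresponds to a smallest significant
correlation of |r| = 0.27 (`min_significant_r()`).

**Confounding diagnostic.** Bonferroni-passing pairs with |r| ≥ 0.5 form a
bipartite graph (expression and methylation probes as nodes). Cell-type
driven structure shows up as large connected components whose probes
separate purified blood-cell reference samples by cell identity
(`celltype_specificity_score()`, an adjusted-Rand operationalization of the
dendrogram check).

**Adjustment.** Traits are residualized on observed cell-count proportions,
or on proportions predicted from methylation by unconstrained least-squares
deconvolution against purified-cell reference profiles (top-k probes per
cell type by a moderated one-vs-rest t), calibrated so the regression of
predicted on observed values has slope 1 and intercept 0. Under a linear
single-confounder model, adjusting on a predictor whose correlation with
the true proportion is `r_pred` leaves a fraction `1 − r_pred²` of the
confounder-driven correlation in place — 44% at r_pred = 0.75, 10% at
r_pred = 0.95 (`residual_confounding_fraction()`).

**Shared genetic control.** For same-chromosome pairs surviving adjustment,
per-probe single-SNP association scans are intersected at p < 10⁻⁵ to call
shared QTLs (best SNPs collected at a relaxed p < 10⁻¹), and genetic
correlations `rG = cov_A / √(V_A1 V_A2)` are estimated by bivariate AI-REML
on a SNP-derived genomic relationship matrix
(`A_jk = (1/M) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1−p_i))`).

## Worked example

```r
library(emcovar)

cfg <- pipeline_config(
  seed = 2026,
  n_families = 80, n_snps = 1500,
  truth = truth_spec(n_expr = 400, n_meth = 1000, n_cell_expr = 80,
                     n_cell_meth = 160, n_shared_pairs = 25,
                     n_latent_expr = 10, n_latent_meth = 20),
  n_markers = 250, max_rg_pairs = 80
)
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   cohort: 422 individuals, 400 x 1000 probes (400,000 tests)
#>   Bonferroni p <= 1.25e-07 (|r| >= 0.253 at n = 422)
#>   significant pairs: 5453 pre-adjustment -> 80 post (68.2-fold reduction)
#>   largest component: 71 of 8 components pre; 0 post
#>   shared QTL: 25/47 same-chromosome pairs share >= 1 QTL

report$rg_summary
#> # A tibble: 3 × 3
#>   stratum                  n mean_abs_rg
#>   <chr>                <int>       <dbl>
#> 1 diff_chrom              28       0.921
#> 2 same_chrom_no_shared    21       0.914
#> 3 shared_qtl              25       0.684
```

Reading the output: before adjustment, thousands of probe pairs pass the
Bonferroni cutoff, almost all of them driven by cell composition (large
graph components). Adjusting on the observed proportions collapses the
count 68-fold; of the surviving same-chromosome pairs, the 25 planted
shared-QTL pairs are all recovered as sharers. Their genetic correlations
average |rG| ≈ 0.68, close to the planted value of 2/3
(`shared_qtl_var / shared_h2 = 0.4 / 0.6`). The non-shared strata show the
boundary-inflated |rG| typical of pairs selected for high phenotypic
correlation when genetic variance is weakly identified — the selection-bias
caveat that applies equally to real cohorts.

Result tables (`report_tables(report)`) expose the significant pairs,
per-pair sharing records, best SNPs and genetic correlations;
`plot_pair_distance()`, `plot_component_sizes()`, `plot_rg_distribution()`
and `plot_proportion_calibration()` visualize each stage.

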