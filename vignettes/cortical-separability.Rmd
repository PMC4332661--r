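---
title: "Methods: group separability of cortical thickness correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group separability of cortical thickness correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortsep)
```

## The model and its assumptions

`cortsep` treats each subject as a 70-vector of mean regional cortical
thickness (mm) on a bilateral Desikan–Killiany-style atlas. The quantity of
interest is not thickness itself but *structural covariance*: the Pearson
correlation, across the subjects of one cohort, between the thickness of two
regions. The pipeline asks whether the case and control cohorts differ in
this correlation structure and, if so, how separable the groups are.

Assumptions worth stating explicitly:

* **Pearson correlation** is used throughout. It is the field standard for
  thickness covariance and is exact for the linear-Gaussian world the
  synthetic generator simulates. No Fisher z-transform is applied before
  differencing (none is standard for this analysis; differences of raw
  correlations are what the per-pair Euclidean distance reduces to).
* **No covariate adjustment** (age, sex, scanner) is applied before
  correlation. Real studies may want to residualize first; the pipeline
  operates on whatever table it is given.
* **Group-level features.** The unit of classification is a subset of six
  subjects, not an individual; nothing here is a diagnostic classifier.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 15 | region pairs kept as features (of 2415 candidates) |
| `g` | 6 | subjects per subset; a within-subset correlation uses n = 6 points |
| `n_subsets_per_cohort` | 500 | subset draws per cohort (1000 rows total) |
| train/test rows | 700/300 | row split in both experiments |
| experiment-2 pools | 40/24 | training subjects (of 64 cases / 39 controls) |
| `cv_folds` | 5 | stratified CV folds for penalty selection |
| penalty grid | 20 values, 10^-3..10^2 | L1 penalties searched on standardized features |
| `n_boot` | 100 | stratified bootstrap replicates for ROC bands |

Subset draws are without replacement within a draw and independent across
draws, so subjects recur across rows — that recurrence is precisely the
identity leakage Experiment 2 is designed to remove.

## The separability estimator

For pooled samples of sizes m and n, the Friedman–Rafsky statistic C is the
number of edges of the Euclidean minimal spanning tree joining points of
different samples. The package reports the divergence estimate
`D = max(0, 1 − C(m+n)/(2mn))` and the separability score `S = (1+D)/2`.
This normalization reproduces the documented `[0.5, 1]` range with both
endpoints attained: identical distributions give `C ≈ 2mn/(m+n)` and
`S ≈ 0.5`; fully separated samples give `C = 1` and `S → 1`. Raw values
below zero (over-mixed samples, possible at small n) are clamped because a
divergence is non-negative by definition.

Numerical choices: the MST is built by Prim's algorithm on the full distance
matrix (O(N²), exact, ample at N = 1000); distance ties are broken by lowest
point index so the tree is deterministic, and with continuous features ties
are measure-zero so C is unaffected in practice; a single MST is used (no
orthogonal-MST averaging). S is invariant under rigid motions and uniform
rescaling of the pooled cloud, which the tests assert.

## The synthetic world

The generator draws each cohort from a multivariate normal: mean 2.5 mm, sd
0.15 mm per region (typical cortical values), background interregional
correlation 0.1, and a planted structure that differs between cohorts.
Normality is the minimal model consistent with a Pearson-correlation
analysis; values are clipped at a 0.5 mm floor only as a guard (a > 13-sigma
event under the defaults — effectively never triggered, and logged if so).

The default scenario (`planted_hub_spec()`) plants one hub region
(`rh_temporalpole`) correlated at `r_case = 0.8` with 15 spoke regions in
cases and `r_control = 0` in controls. A design point discovered during
implementation: a hub with 15 partners at r = 0.8 over a 0.1 background is
*not a correlation matrix* — its smallest eigenvalue is about −1.7, and any
nearest-positive-definite repair drags the planted correlations down to
≈ 0.42, a 0.38 perturbation. The scenario is therefore constructed from a
single latent factor (hub loading 1.0, spoke loadings 0.8), which realizes
every hub–spoke correlation at exactly 0.8 and *implies* spoke–spoke
correlations of 0.64 in cases. That implication is not a nuisance: real
structural covariance hubs behave the same way (partners of a common hub
co-vary). The implied pairs are planted explicitly, making the target
exactly positive definite (smallest eigenvalue ≈ 0.03, no repair).

For arbitrary user-specified planted pairs, `build_covariance()` keeps a
generic contract: assemble the target, repair by eigenvalue clipping (floor
1e-6) with unit-diagonal renormalization if needed, report the maximum
absolute correlation perturbation, and *error* if it exceeds 0.05 — silent
large repairs would mean simulating a different world than requested. The
repair is checked in the tests against a separately implemented nearest-PD
oracle.

What the generator does **not** emulate: age/sex/site covariates,
non-Gaussian tails, spatially structured noise, hemispheric asymmetries, or
the study's true (unpublished) covariance. A green test on synthetic data
therefore establishes that the *machinery* behaves as specified under a
known world — not that any particular clinical effect size is reproduced.

## Classifier choices

"Sparsity-constrained linear classifier" is concretized as L1-penalized
logistic regression (glmnet): a linear decision function whose weights are
driven to exact zeros, with logistic loss for calibrated scores. The penalty
is selected by stratified k-fold CV maximizing mean validation AUC, ties
going to the sparser model, then the model is refit on all training rows.
Features are standardized with training-set center/scale only, which makes
predictions invariant to affine rescaling of any input feature. An L1 hinge
loss variant was considered and dropped: no solver in the dependency set
provides it, and it is secondary to the protocol comparison the package
exists for. `"case"` is the positive class; evaluation is threshold-free
(ROC + AUC + interpolated TPR at fixed FPR), with percentile bootstrap bands
from stratified resampling of test rows.

Experiment 2 allocates the 700/300 row totals evenly across cohorts (odd
remainder to cases) — the protocol specifies only the totals. Feature
selection uses the full cohorts in both experiments, mirroring the published
protocol; note this leaves selection-level leakage in Experiment 2 (only
row-generation leakage is removed). The subject-disjointness audit
(`audit_subject_disjoint()`) is a hard assertion on every run.

## Known limitations

* **Exact top-15 recovery is noise-limited.** With cohorts of 64 and 39, the
  sampling sd of one pair's correlation difference is about
  `sqrt(1/61 + 1/36) ≈ 0.20`; the maximum over ~2400 null pairs is then
  0.7–0.85, overlapping the planted differences (0.8 ± 0.17). Demanding all
  15 planted pairs in the top 15 in ≥ 95% of seeds is therefore
  unattainable at these sample sizes — measured recovery is ~8–12 of 15
  pairs per seed, with the selected-but-unplanted pairs coming from the
  correlated hub cluster, so the *selected* features remain informative and
  the separability plateau (criterion 5) is unaffected. The corresponding
  acceptance test is left failing rather than weakened.
* The hub scenario's spoke–spoke correlations (0.64) mean "the 15 planted
  pairs" and "the 15 most different pairs" are not identical populations:
  105 implied pairs differ by 0.54 and legitimately compete.
* The per-hemisphere region list carries 35 labels by convention (34
  standard thickness-bearing Desikan–Killiany labels plus
  `corpuscallosum`); region *order* is a package convention — published
  "feature numbers" from other sources cannot be mapped onto it.
* Run-to-run determinism is guaranteed given one master seed
  (`derive_seed()` fans out stage seeds) on a single platform/BLAS; MST
  tie-breaks and glmnet paths are deterministic.

## A scaled-down end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(n_subsets_per_cohort = 100L,
                       n_train_rows = 140L, n_test_rows = 60L,
                       n_boot = 25L)
report <- run_pipeline(cfg, seed = 1)
report$curve$separability       # cumulative separability, 15 values
report$experiment1$auc          # overlapping-subject protocol
report$experiment2$auc          # subject-disjoint protocol
```

Every number this vignette cites (0.5/1 endpoints, the 0.99 plateau, the
recovery shortfall, PD eigenvalues) is computed by the test suite or
`scripts/acceptance.R`, not asserted by hand.
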