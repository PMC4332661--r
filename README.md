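# cortsep

Group separability of interregional cortical thickness correlations.

## The problem

Regional cortical thickness (mm, one value per atlas region per subject)
covaries between brain regions across subjects; these interregional Pearson
correlations — *structural covariance* — differ between clinical groups.
`cortsep` implements a complete, testable pipeline for asking *how separable
two cohorts are* in structural-covariance space when each cohort is
summarized not per subject but per small subject group:

1. **Cohort correlation matrices.** For each cohort (e.g., 64 cases, 39
   controls) compute the 70 x 70 matrix of interregional Pearson correlations
   of regional thickness across subjects.
2. **Feature selection.** Rank all 2415 off-diagonal region pairs by the
   absolute cross-cohort difference `|r_case − r_control|` (the per-pair
   Euclidean distance between the two correlation structures) and keep the
   top 15.
3. **Subset features.** Draw 500 random subsets of 6 subjects per cohort and
   recompute the 15 pair correlations within each subset, giving a labeled
   1000 x 15 feature matrix.
4. **Separability.** Estimate the Henze–Penrose divergence between the two
   subset clouds with the Friedman–Rafsky statistic: build the Euclidean
   minimal spanning tree of the pooled points, count the `C` edges joining
   points from different cohorts, and set

   ```
   D = max(0, 1 − C(m+n)/(2mn)),   S = (1 + D)/2  ∈  [0.5, 1]
   ```

   `S = 0.5` means the cohorts cannot be told apart, `S = 1` means they are
   completely separable. A cumulative curve adds the 15 features one at a
   time.
5. **Classification.** Confirm with an L1-penalized (sparsity-constrained)
   linear classifier under two protocols: **Experiment 1** splits the 1000
   subset rows 700/300 at random (subjects recur on both sides); **Experiment
   2** first splits the *subjects* (40 of 64 cases, 24 of 39 controls for
   training) and generates the 700 training / 300 test rows from disjoint
   subject pools, eliminating identity leakage. Both are evaluated by ROC
   with 100 stratified bootstrap replicates.

Because no subject-level MRI data ship with the package, a synthetic
generator (`planted_hub_spec()`, `simulate_cohorts()`) produces two
multivariate-normal cohorts with a planted hub-correlation structure (a
single region strongly correlated with 15 spokes in cases only), emulating
the temporal-pole-centred covariance difference the pipeline is designed to
detect. Every stage is unit-tested against independent oracles; see
`vignettes/cortical-separability.Rmd` for the model, parameter, and design
discussion.

## Worked example

```r
library(cortsep)
cfg <- pipeline_config()          # study defaults: k=15, g=6, 500 subsets, ...
report <- run_pipeline(cfg, seed = 7, out_dir = "cortsep_out")
```

which logs (abridged):

```
stage input: synthetic cohorts
  case n=64 control n=39
stage features: top-15 pairs by absolute correlation difference
stage separability: cumulative Henze-Penrose curve
  final separability = 0.9990
stage experiment 2: subject-disjoint pools 40/24
  subject-disjointness audit passed
  AUC experiment1=1.000 experiment2=0.999
```

`report$curve` holds the 15-point separability curve (here rising to 0.999:
with 15 hub correlations planted at r = 0.8 vs 0, six-subject subsets are
essentially perfectly separable, matching the strong-effect regime where the
curve "plateaus above 0.9"). `report$features` lists the selected pairs —
under the planted-hub defaults they all involve the hub/spoke cluster around
`rh_temporalpole`. `cortsep_out/` contains correlation heatmaps, the
feature table, the curve, the PCA embedding, both ROC curves with bootstrap
bands, a machine-readable `results.json`, and a run log. Experiment 1
slightly exceeds Experiment 2 — the overlapping protocol's identity leakage —
and the gap widens at moderate effect sizes (`planted_hub_spec(r_case = 0.5)`).

Command line (same stages):

```sh
./exec/cortsep simulate --out-dir sim --seed 7
./exec/cortsep run --config config.json --seed 7 --out-dir out
```

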