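# hubcent

Brain-network hubs — regions whose activity is densely correlated with the
rest of the brain — reorganise when people engage a cognitively demanding
task, and their organisation changes over child and adolescent development.
`hubcent` implements a complete, tested pipeline for studying this with
fMRI: voxel-wise **eigenvector centrality mapping (ECM)** of rest and
working-memory (n-back) runs, **spatial ICA** of the resulting centrality
maps into network components with per-run subject weights, **dual-regression
GLMs** for task activation, component-wise statistics relating centrality
change to task condition, age and in-scanner performance, and **voxel-wise
permutation inference with TFCE**. A synthetic-cohort generator with planted
network structure and known effect sizes stands in for restricted-access
developmental cohort data and powers all validation.

The package is aimed at researchers who want a desk-scale, fully
reproducible reimplementation of this analysis style — to probe its
statistical behaviour, to validate methodological variations against planted
ground truth, or to run it on their own NIfTI data.

## The method

For each run, every in-mask voxel time series is detrended, high-pass
filtered (0.01 Hz) and standardized. Eigenvector centrality assigns voxel
*i* the *i*-th entry of the leading eigenvector of the absolute correlation
matrix,

    A_ij = | corr(x_i, x_j) |,   A v = λ v,   EC = v ≥ 0,

so positive and negative correlations carry equal weight and, by
Perron–Frobenius, the map is nonnegative. The eigenvector is found by power
iteration with blockwise matrix–vector products, so the V×V matrix is never
stored (peak memory O(block_rows × V)).

The per-run EC maps (rows) are stacked, z-scored, and decomposed with
fixed-point spatial ICA (logcosh contrast) into K spatially independent
component maps with per-run mixing weights. For each component, the
task-minus-rest difference of a subject's weights is the per-component
centrality change score. These feed:

* one-sample t tests (task effect on centrality),
* age regressions on task and rest weights (sex-adjusted),
* task-by-age interaction and performance regressions
  (hit rate, false-alarm rate, d′ = Φ⁻¹(hit) − Φ⁻¹(fa)),
* Benjamini–Hochberg FDR across components,
* the correlation, across components, between the task effect on centrality
  and the dual-regression activation contrast
  (mean of 1-back and 2-back betas minus the 0-back beta).

Voxel-wise inference on the same EC maps uses one-sample and Freedman–Lane
permutation schemes with threshold-free cluster enhancement
(E = 0.5, H = 2) and max-statistic FWE correction, two-tailed.

## Worked example

Simulate a 24-subject cohort (two runs each, planted hub and task-negative
sensory networks plus artifact sources) and run the whole pipeline:

```r
library(hubcent)

cfg <- pipeline_config(
  synthetic = cohort_config(n_subjects = 24, grid_dims = c(16L, 16L, 10L),
                            k_networks = 4L, k_artifacts = 2L, seed = 42),
  ica_k = 6, n_perm = 200)
bundle <- run_pipeline(cfg)
print(bundle)
#> <results_bundle> 48 EC maps, 4/6 components retained, 36 stat rows,
#>   voxelwise tests: task_diff, age_diff
```

Match recovered components to the planted networks and look at the key
families:

```r
M <- t(sapply(1:6, function(j)
  bundle$ground_truth$atlas$maps[, , , j][bundle$mask$idx]))
mm <- match_components(bundle$decomposition$spatial_maps, M)
labels <- setNames(bundle$ground_truth$atlas$labels[mm$ref],
                   sprintf("comp_%d", mm$est))
st <- bundle$stat_table
st$network <- labels[st$component]
subset(st, family %in% c("task_effect", "age_rest", "perf_dprime") &
           network %in% c("hub", "sensory"))
#>    component      family estimate      t        p  n        q significant network
#> 1     comp_2 task_effect   0.2622  3.325 2.95e-03 24 5.89e-03        TRUE     hub
#> 2     comp_4 task_effect  -0.2361 -5.730 7.77e-06 24 3.11e-05        TRUE sensory
#> 9     comp_2    age_rest   0.0452  3.904 8.17e-04 24 3.27e-03        TRUE     hub
#> 10    comp_4    age_rest   0.0063  0.591 5.61e-01 24 5.61e-01       FALSE sensory
#> 25    comp_2 perf_dprime   0.2551  2.149 4.40e-02 24 1.76e-01       FALSE     hub
#> 26    comp_4 perf_dprime  -0.0492 -0.740 4.68e-01 24 4.68e-01       FALSE sensory
```

The planted pattern is recovered: the hub component's centrality rises under
task (t = 3.3, FDR-significant), the sensory component's falls (t = −5.7),
and hub centrality increases with age at rest (t = 3.9). The hub–d′
association has the planted positive sign (t = 2.1); at n = 24 it does not
survive FDR — at the generator's reference size of n = 40 it reliably does.
Across components, task effects on centrality track activation:

```r
ec_activation_correlation(st)
#> EC-activation coupling across components: r = 1.00 (p = 0.00282, k = 4)
```

With `out_dir` set, `run_pipeline()` also writes every artifact to disk
(NIfTI maps, TSV tables, JSON sidecars and a provenance manifest) and
resumes completed stages on rerun. A thin CLI wraps the same functions:

```sh
exec/hubcent run-all --out results_dir --seed 1 --subjects 24
```

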