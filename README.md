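# subtypr

Deep ensemble clustering of voxelwise resting-state ALFF maps into stable
neurobiological patient subtypes.

Psychiatric diagnoses (schizophrenia, bipolar disorder, major depression)
overlap heavily in their resting-state functional alterations, and groups
defined by diagnosis alone are biologically heterogeneous. `subtypr`
implements a trans-diagnostic subtyping workflow for per-subject ALFF
(amplitude of low-frequency fluctuations, 0.01–0.08 Hz) volumes:

1. **Voxelwise screen** — per-voxel OLS GLM `ALFF ~ group + sex + age`,
   two-sided test on the group coefficient at voxel *p* < 0.001 with
   cluster-level correction at *p* < 0.05 (Gaussian random field theory, or
   a Freedman–Lane permutation null of the maximal cluster extent). The
   surviving voxels form the subjects × voxels feature matrix.
2. **Embedding** — a fully connected autoencoder per target dimension
   *d* ∈ [2, 10], encoder sizes halving from the largest power of two below
   the input width down to 32 and then *d*
   (2175–2048–1024–512–256–128–64–32–*d* at full scale), ReLU hidden
   layers, linear bottleneck/output, minibatch Adam on the reconstruction
   MSE. Nine low-dimensional views of the same patients.
3. **Ensemble consensus** — complete-linkage hierarchical clustering
   (Euclidean distance) of each view, exact label alignment across views,
   and a per-subject plurality vote.
4. **Robustness merging** — the embed/cluster stage is rerun *J* = 6 times
   with fresh seeds; each cluster *i* gets a robustness index

   *R*<sub>*i*</sub> = |∩<sub>*j*</sub> *C*<sub>*i*</sub><sup>*j*</sup>| / |∪<sub>*j*</sub> *C*<sub>*i*</sub><sup>*j*</sup>|

   over its matched member sets *C*<sub>*i*</sub><sup>*j*</sup> across runs;
   while any *R*<sub>*i*</sub> ≤ δ (default 0.8) the two least-robust
   clusters are merged and the indices recomputed. Survivors are subtypes.
5. **Validation** — subtype-vs-control *t*/*p*/Cohen's-*d* maps with
   cluster correction, Welch *t*-tests with Benjamini–Hochberg FDR on
   clinical factor scores, and logistic regression of subtype membership on
   continuous risk scores with Nagelkerke pseudo-*R*².

Because cohorts of this kind are not publicly distributable, the package
includes a synthetic-cohort generator (`sim_config()`, `generate_cohort()`)
with planted ground truth: two patient subtypes with sign-opposed
frontal/posterior ALFF imbalance on top of a shared case–control
alteration, covariate effects, and spatially smoothed Gaussian noise. See
the methods vignette (`vignettes/subtyping-methods.Rmd`) for the model and
every numerical choice.

## Worked example

```r
library(subtypr)

cfg <- pipeline_config(
  sim  = sim_config(n_patients = 200, n_controls = 100),
  seed = 11)
res <- run_pipeline(cfg)
res
#> <subtype_pipeline> 300 subjects, 297 selected voxels, k=2, 2 final subtypes, recovery ARI 1.000
res$report
#> <robustness_report> 2 initial clusters -> 2 subtypes after 0 merges (delta = 0.8)
#>   final robustness: 1.000, 1.000
```

297 of ~2,100 mask voxels survive the screen; the silhouette criterion
picks *k* = 2; both consensus clusters are perfectly stable across the six
runs (*R* = 1.0), so nothing is merged; and the final labels match the
planted subtypes exactly (adjusted Rand index 1.0 against the held-out
truth table).

The validation battery characterises the discovered subtypes (label order
is arbitrary — here discovered subtype 2 is the medication-responsive,
risk-score-associated one):

```r
glance(res$validation$scores$subtype_2)
#> # A tibble: 1 × 5
#>   n_scores n_significant alpha best_score best_r2
#>      <int>         <int> <dbl> <chr>        <dbl>
#> 1        5             1 0.004 score_1     0.0596

tidy(res$validation$medication$subtype_2)[, c("factor", "cohens_d", "p.adjusted", "significant")]
#> # A tibble: 4 × 4
#>   factor   cohens_d p.adjusted significant
#>   <chr>       <dbl>      <dbl> <lgl>
#> 1 factor_1   -1.01   0.0000106 TRUE
#> 2 factor_2   -0.620  0.00254   TRUE
#> 3 factor_3   -0.629  0.00254   TRUE
#> 4 factor_4   -0.797  0.000397  TRUE
```

Only the planted risk score (`score_1`) associates with the affected
subtype (Nagelkerke *R*² ≈ 0.06 at α = 0.004), and medicated patients in
that subtype score significantly lower on every clinical factor — the
planted medication-response pattern. Each result type also has `tidy()`,
`glance()` and `autoplot()` methods (loss curves, agreement histograms,
robustness trajectories, `plot_voxel_map()` for statistic maps).

A command-line interface wraps the same functions:

```sh
exec/subtypr simulate --config sim.yml --out cohort/
exec/subtypr select   --cohort cohort/ --out sel/
exec/subtypr embed    --features sel/features.tsv --out emb/
exec/subtypr cluster  --latents emb/ --k auto --out cons/
exec/subtypr run      --config pipeline.yml --out run1/
```

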