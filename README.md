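# dmsubtype

Data-driven subtyping of recent-onset type 2 diabetes, with genetic,
lipidomic and cardio-renal characterisation of the subgroups.

Type 2 diabetes is clinically heterogeneous. A practical way to stratify
it is to cluster patients on a handful of routine clinical variables —
diabetes onset age, BMI, HbA1c, and the HOMA2 indices of beta-cell
function (HOMA2-B) and insulin resistance (HOMA2-IR) — and then ask
whether the resulting subgroups differ in genetic background, molecular
profile and long-term complication risk. `dmsubtype` implements that full
pipeline for epidemiologists and biostatisticians:

- **Subtyping** — standardise the five classifiers (log transform for the
  HOMA indices), partition by k-means (Lloyd + k-means++, best of
  restarts), choose k by majority voting over twelve internal validity
  indices, and quantify robustness with bootstrap Jaccard stability
  (`standardize()`, `cluster_cohort()`, `select_k_majority_vote()`,
  `jaccard_stability()`). External cohorts are assigned by minimal
  Euclidean distance to reference centroids (`assign_by_reference()`),
  and a sex-residualised sensitivity analysis plus Cohen's-kappa
  concordance are built in (`residualize_on_covariate()`,
  `concordance()`).
- **Polygenic risk scores** — weighted risk-allele dosage sums
  (`compute_prs()`) regressed on subgroup membership with covariate
  adjustment (`associate_prs()`).
- **Lipidomics** — a discovery–validation screen: signal-to-noise filter,
  log-scale batch correction, per-species Kruskal–Wallis tests with a
  Bonferroni gate (0.05 / m; 1.59e-4 at m = 315), nominal replication,
  pairwise log-fold contrasts and a heatmap export (`filter_snr()`,
  `batch_correct()`, `kw_screen()`, `replicate_screen()`,
  `pairwise_contrast()`, `heatmap_matrix()`).
- **Outcomes** — derivation of progressive chronic kidney disease from
  longitudinal eGFR (a confirmed decline of ≥40% from baseline,
  confirmation ≥3 months later), incidence rates per 1000 person-years
  with exact Poisson intervals, Kaplan–Meier, logrank, and Cox
  proportional hazards with Efron ties and Schoenfeld diagnostics
  (`derive_progressive_ckd()`, `incidence_rate()`, `km_estimate()`,
  `logrank_test()`, `cox_fit()`, `schoenfeld_ph_test()`).
- **Synthetic cohorts** — because cohorts of this kind are not public,
  `table1_specs()` + `simulate_clinical_cohort()` generate a calibrated
  687-participant cohort (three subgroups: MOD 307, SIRD-RII 130,
  MARD-II 250; Gaussian marginals for mean ± SD variables, lognormals
  fitted from median/IQR for skewed ones), with companion generators for
  genotypes, lipidomes, event times and eGFR trajectories, all with
  planted, recoverable effects. `run_pipeline()` chains everything from
  one master seed.

Results are tibbles; fitted objects have `tidy()`/`glance()` and
`autoplot()` methods.

## Worked example

```r
library(dmsubtype)

cohort <- simulate_clinical_cohort(seed = 1)   # 687 synthetic participants
model  <- cluster_cohort(cohort, k = 3, restarts = 25, seed = 2)
tidy(model)
#> # A tibble: 3 × 8
#>   cluster subgroup  size onset_age    bmi  hba1c homa2b homa2ir
#>     <int> <chr>    <int>     <dbl>  <dbl>  <dbl>  <dbl>   <dbl>
#> 1       1 MOD        280    0.0248  0.485 -0.412  0.794   0.352
#> 2       2 MARD-II    265    0.471  -0.693 -0.310 -0.354  -0.754
#> 3       3 SIRD-RII   142   -0.928   0.338  1.39  -0.905   0.714

std  <- standardize(cohort)
jaccard_stability(std$x, model, B = 200, seed = 3)
#> <stability_report> B = 200 bootstraps
#> Mean Jaccard per cluster: 0.953, 0.947, 0.949
```

Reading the centroid table: one cluster (41% of the cohort here) combines
high BMI with preserved beta-cell function (high HOMA2-B) — the mild
obesity-related subgroup (MOD). The small cluster (21%) pairs the highest
HbA1c with high insulin resistance and young onset — severe
insulin-resistant diabetes with relative insulin insufficiency
(SIRD-RII). The third (39%) is older at onset, lean, and
insulin-insufficient (MARD-II). All three clusters are stable under
resampling (mean Jaccard ≈ 0.95, well above the conventional 0.85
dissolution threshold). `autoplot(model)` draws the centroid profiles;
`run_pipeline(default_scenario(), seed = 1)` adds the genetic, lipidomic
and outcome stages on top.

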