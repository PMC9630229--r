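---
title: "Subtyping recent-onset type 2 diabetes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtyping recent-onset type 2 diabetes: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsubtype)
library(dplyr)
```

## The analysis in one paragraph

`dmsubtype` implements a clinical-variable subtyping pipeline for
recent-onset type 2 diabetes. Five classifiers — diabetes onset age, BMI,
HbA1c, and log-transformed HOMA2-B (beta-cell secretory function) and
HOMA2-IR (insulin resistance) — are standardised to mean 0 / SD 1 and
partitioned by k-means. The number of clusters is chosen by majority voting
over twelve internal validity indices, and cluster robustness is quantified
by bootstrap Jaccard stability. The resulting subgroups are then
characterised on three axes: polygenic risk scores (weighted risk-allele
dosage sums regressed on subgroup membership), a discovery–validation
differential lipidomics screen with Bonferroni gating, and cardio-renal
outcomes (a confirmed 40%-eGFR-decline kidney endpoint, incidence rates
with exact Poisson intervals, Kaplan–Meier/logrank, and Cox proportional
hazards with Schoenfeld diagnostics). Because patient-level cohorts of this
kind are not public, the package ships a synthetic-cohort generator whose
defaults are calibrated to the published baseline characteristics of a
687-participant South East Asian cohort, so every stage runs and is tested
end-to-end on data with known planted structure.

## The synthetic cohort: what it emulates and what it does not

`table1_specs()` encodes three subgroups — mild obesity-related diabetes
(MOD, n = 307), severe insulin-resistant diabetes with relative insulin
insufficiency (SIRD-RII, n = 130), and mild age-related diabetes with
insulin insufficiency (MARD-II, n = 250) — with one marginal distribution
per clinical variable: Gaussians for variables reported as mean ± SD and
lognormals for skewed variables reported as median (IQR). The lognormal
calibration is closed-form: `mu = log(median)`,
`sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`. This reproduces the
median and the log-scale IQR width exactly; when a published quartile pair
is not symmetric around the median on the log scale (a shape a
two-parameter lognormal cannot represent), the individual quartiles are
matched only approximately. Tests therefore pin the median and the
`q3/q1` ratio, not each endpoint.

Variables are drawn independently within subgroup, because the baseline
table publishes only marginals; an optional correlation structure is not
defaulted on. This matters for interpretation: real clinical classifiers
are correlated (HOMA2-B and HOMA2-IR are both functions of fasting glucose
and C-peptide), and correlation typically sharpens cluster structure.
Passing tests on the independent-marginal cohort show that the pipeline
recovers planted structure of the published magnitude; they do not show
how much easier or harder a real correlated cohort would be. Subgroup
sizes are fixed at the published counts by default (`fixed_sizes = TRUE`)
so design-stage proportions are exact; a multinomial mode exists.

Genotypes are Binomial(2, f) risk-allele dosages from synthetic weight
panels (invented variant ids and frequencies, effect sizes of realistic
log-odds-ratio magnitude); a planted mean score shift for a subgroup is
realised by the minimum-norm frequency perturbation
`f + delta * w / (2 * sum(w^2))`. The lipidome is log-normal per species
with planted subgroup shifts expressed in within-group SD units and
additive log-scale batch offsets. Event times are exponential by default
(a Weibull shape is exposed; Cox hazard-ratio recovery is shape-agnostic),
with per-participant administrative censoring drawn from 5.9–8.7 years to
emulate staggered recruitment with a median follow-up near 7.3 years.
eGFR trajectories decline geometrically with multiplicative lognormal
measurement noise, floored at 5 ml/min/1.73m².

## Clustering conventions

*k-means flavour.* Lloyd iterations from k-means++ starts, best of 25
restarts by within-cluster sum of squares, labels renumbered by descending
cluster size. An empty cluster is re-seeded at the point farthest from its
assigned centroid. Differences between Lloyd and other k-means variants
are absorbed by best-of-restarts; correctness is asserted against an
exhaustive best-WSS bipartition oracle on small instances rather than by
matching any particular implementation.

*Standardisation.* Sample SD (n − 1) by default, population SD available.
Fitted scaling parameters travel with the model so external cohorts are
projected onto the discovery scale rather than re-standardised.

*The 12-index electorate.* Calinski–Harabasz, average silhouette width,
Davies–Bouldin, Dunn, C-index, Ball–Hall, the Hartigan rule,
Krzanowski–Lai, McClain–Rao, point-biserial, Ratkowsky–Lance and Xie–Beni,
each voting under its own optimality direction, modal k winning and ties
going to the smallest k. Three conventions needed deciding:

- Difference-based indices (Ball–Hall, the Hartigan fallback) are
  evaluated *within the searched k-range*, the convention of the
  established majority-voting tool in this field. Anchoring them at k = 1
  (outside any user's candidate set) makes Ball–Hall vote for the smallest
  k unconditionally, which is degenerate.
- The Hartigan rule proper (smallest k with statistic ≤ 10) rarely fires
  on overlapping clinical data; when it does not, the index votes at its
  within-range elbow instead of abstaining.
- An index undefined at some k (e.g. a zero denominator) abstains for that
  k; an index undefined everywhere abstains entirely.

On the calibrated 687-participant cohort the electorate is genuinely
split: variance-ratio-style indices (Calinski–Harabasz, Ratkowsky–Lance,
Hartigan, usually Davies–Bouldin and Krzanowski–Lai) prefer k = 3, while
silhouette, Xie–Beni and point-biserial prefer k = 2 and the
pair-distance indices (C-index, McClain–Rao) drift to the top of the
range. Under independent marginals the vote lands on k = 3 in roughly 70%
of seeds, short of the 90% the published analysis would suggest; we
attribute the gap to the missing classifier correlations (see
*Limitations*), report it as measured, and do not adjust the electorate or
the generator to close it.

*Bootstrap Jaccard stability.* Nonparametric row resampling, re-fit at the
same k, greedy per-original-cluster matching by maximal Jaccard index with
membership counted over distinct original rows. A replicate in which an
original cluster has no resampled member is excluded from that cluster's
mean: it carries no information about the cluster, and scoring it 0 would
make the stability of even a perfectly separated cluster depend on the
resampling lottery. On the calibrated cohort all three clusters score
≈ 0.92–0.96 with B = 500 (scaled down from 5000 for runtime; B is a
parameter).

*Phenotype naming.* For k = 3: the cluster with the highest standardised
HbA1c centroid is SIRD-RII; of the rest, the higher onset-age centroid is
MARD-II; the remainder is MOD. The rule is overridable and falls back to
generic names with a warning off k = 3 or with degenerate centroids.

*Reference assignment.* External cohorts are assigned to per-cluster raw
means of a chosen variable set (e.g. BMI, onset age, HbA1c and the
triacylglycerol/HDL ratio when HOMA indices are unavailable) by minimal
Euclidean distance. By default both centroids and rows are standardised
with the reference cohort's scaling first — otherwise BMI and onset-age
units dominate the metric — with a raw-scale mode for strict replication
of centroid-matrix approaches.

## Association and screening conventions

*Polygenic scores.* `score = sum(weight * dosage)` with dosages oriented
to the risk allele; a counted-allele map flips orientation where a file
counts the other allele. Missing dosages are mean-imputed per variant by
default (strict mode errors). Association is ordinary least squares of the
score on subgroup indicators (MOD reference) plus sex and three principal
components, with Wald intervals; principal components are consumed as
plain covariate columns, their computation being out of scope.

*Top-percentile flag.* The top `floor(f * n)` scores are flagged with ties
at the threshold kept — the convention that flags exactly 5 of 100
distinct scores at f = 0.05 and everyone when all scores tie.

*Lipid screen.* Species with signal-to-noise ratio < 3 are removed
(exactly 3 is kept). Batch correction is per-species median centering on
the log scale re-centred to the global median — chosen for robustness,
positivity preservation and invertibility; the upstream assay's own
correction is unspecified, and a passthrough mode exists. The discovery
stage is a tie-corrected Kruskal–Wallis test per species with the
Bonferroni threshold `0.05 / m`, where `m` is the post-filter species
count (315 in the reference configuration, threshold 1.59e-4). Only
discovery-passing species are tested in the validation cohort at nominal
p < 0.05, direction-agnostic. Pairwise contrasts are OLS of log
concentration on subgroup indicators, so coefficients are log fold
differences versus MOD.

## Outcome conventions

*Progressive CKD.* Event at the first measurement at or below 60% of
baseline eGFR that is confirmed by another qualifying measurement at least
0.25 years (3 months) later; unconfirmed dips do not count; otherwise
censored at the last measurement. The event is timed at the first
qualifying measurement, not its confirmation — the alternative is a
documented switch, and the rule is monotone: later confirming data can
only create events, never remove them.

*Rates and survival.* Incidence is events per 1000 person-years with the
exact (Garwood) chi-square interval, lower bound 0 at zero events.
Kaplan–Meier, logrank and Cox fits delegate to the `survival` package —
the standard estimators are not this package's contribution — with Efron
tie handling, ethnicity coded against its largest level, and
proportional-hazards diagnostics via scaled Schoenfeld residuals
(Grambsch–Therneau). Tests verify the Cox path against a brute-force
partial-likelihood grid search and the logrank statistic against a
hand-computed O−E/V oracle, so the delegation is cross-checked, not
assumed.

## Problem sizes and reproducibility

The packaged scenario runs the full pipeline on n = 687 with B = 500
bootstraps, a 315-species lipidome (75 discovery-planted, 45
validation-planted species at 1.5 within-group SD), and two planted
outcomes; hazard-ratio recovery checks use n = 5000 with 10-seed
ensembles. A single master seed fans out to per-stage seeds through a
fixed affine rule (`stage_seed()`), so any stage can be re-run in
isolation and a full `run_pipeline()` is bit-reproducible given its seed.

## Limitations

- Independent within-subgroup marginals understate the separation real
  correlated classifiers would provide; the majority-vote criterion is the
  one place this visibly bites (see above).
- The lognormal family cannot represent log-asymmetric quartile triples,
  so a few published IQR endpoints are reproduced only to a few per cent.
- Synthetic weight panels are structurally realistic but invented; no
  linkage disequilibrium, no genotype-derived principal components.
- No missing-data handling in the classifiers (rows with missing values
  are rejected), no competing risks, no time-varying covariates.
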