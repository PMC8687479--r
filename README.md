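# tepflow

**tepflow** analyses EEG responses to single-pulse transcranial magnetic
stimulation (TMS) as predictors of psychological resilience to sustained
stress. A TMS pulse is a brief, controlled cortical perturbation; the
evoked EEG response (the TMS-evoked potential, TEP) quantifies how the
stimulated circuit handles an insult. The package asks, end to end,
whether that response — recorded at the left dorsolateral prefrontal
cortex (DLPFC), with the left inferior parietal lobule (IPL) as a control
target — separates people who later stay mentally stable ("resilient")
from those whose anxiety/depression scores rise ("vulnerable"), and
whether it predicts their mental-health outcome.

It is aimed at TMS-EEG and biostatistics researchers who want the
statistical machinery of this design as tested, reusable code: no human
recordings ship with the package; a synthetic cohort generator with the
assumed statistical structure stands in for them, so every stage is
verifiable.

## What it computes

* **Reactivity measures** (`gmfa`, `local_response`, `auc`,
  `baseline_activity`, `score_subject`): the global mean field amplitude
  GMFA(t) = sqrt(Σᵢ(Vᵢ(t) − V̄(t))²/N); the z-scored rectified local ROI
  response z(t) = (s(t) − μ)/σ with μ, σ from the −500..−3 ms baseline;
  trapezoidal AUCs over 15–400 ms as scalar predictors.
* **Classification** (`classify_resilience`): resilient iff every pandemic
  PHQ-4 total ≤ the pre-pandemic total; `screen_positive` implements the
  PHQ-2/GAD-2 ≥ 3 screening rule; `mean_pandemic_score` the regression
  response.
* **Group comparison** (`cluster_permutation_test`): pointwise
  vulnerable-vs-resilient differences d(t), permutation p-values with
  add-one correction, clusters of contiguous p < α samples judged on
  *both* size and mass Σ|d(t)| against the 95th percentile of a
  max-statistic (or pooled) permutation null; exact enumeration for small
  groups.
* **Prediction** (`run_model_suite`): full (8-predictor), reduced
  (local reactivity + education), IPL-control and reduced+baseline OLS
  models on a Box-Cox transformed response (profile-likelihood λ over
  [−5, 5]); likelihood-ratio test χ² = n·ln(RSSᵣ/RSS_f), AIC/BIC,
  sequential (Type-I) variance decomposition, Lilliefors residual
  normality with Monte-Carlo p, VIF/Durbin-Watson/Breusch-Pagan
  diagnostics.
* **Synthesis** (`sim_config`, `simulate_cohort`): evoked series as
  Gaussian-bump components plus AR(1) noise, with a late (~230 ms)
  component whose amplitude grows with latent vulnerability on DLPFC ROI
  vertices only; PHQ-4 trajectories, PSS-14 stress scores and demographics
  with calibrated couplings (see the methods vignette).

## Worked example

Simulate a 74-subject cohort (here with a spatially reduced profile so the
example runs in seconds), classify it, compare the groups' local DLPFC
response, and fit the model suite:

```r
library(tepflow)

cfg <- sim_config(n_subjects = 74, epoch = c(-1000, 500),
                  n_roi = 25, n_sensors = 16)
sim    <- simulate_cohort(cfg, seed = 5)
labels <- classify_cohort(sim$cohort)
table(labels$label)
#> resilient vulnerable
#>        35         39

roi <- make_roi("DLPFC", cfg)
lab <- setNames(labels$label, labels$subject_id)
ids <- sim$cohort$subject_id[sapply(sim$cohort$completed_targets,
                                    function(v) "DLPFC" %in% v)]
series <- lapply(ids, function(id)
  local_response(sim$teps[[id]]$DLPFC$source, roi))
names(series) <- ids

ct <- cluster_permutation_test(series[lab[ids] == "vulnerable"],
                               series[lab[ids] == "resilient"],
                               n_perm = 1000, seed = 42)
ct
#> <cluster_test> 32 vs 24 series, 1000 perms (max_per_perm), alpha 0.05
#>   cluster 17..18 ms: size 2, magnitude 1.37
#>   ...
#>   cluster 191..256 ms: size 66, magnitude 179  [survives]
#>   ...
```

The only cluster surviving correction spans 191–256 ms — the late local
response window where the generator plants the vulnerability effect
(its exact extent varies across simulated cohorts). The regression stage:

```r
scores <- score_cohort(sim, cfg)
report <- run_model_suite(sim$cohort, scores, seed = 42)
report
#> <tep_report>
#>                  model  n    aic   bic  r2adj lambda
#>             full_dlpfc 56  98.63 118.9 0.2899  0.175
#>          reduced_dlpfc 56  98.08 106.2 0.2275  0.175
#>               full_ipl 55 122.84 142.9 0.1408  0.248
#>  reduced_plus_baseline 56 100.03 110.2 0.2134  0.175
#> LRT full vs reduced DLPFC: chi2(6) = 11.446, p = 0.0755
#> Reduced-model variance decomposition (%):
#>       local_auc education_years       Residuals
#>           12.68           12.88           74.44

report$fits$reduced_dlpfc
#> <tep_fit> reduced_dlpfc n = 56, 2 predictors
#>   F(2, 53) = 9.1, p = 0.000401, R2adj = 0.227
#>   AIC = 98.08, BIC = 106.18, logLik = -45.04, Box-Cox lambda = 0.175
#>              term  estimate       se     t        p
#> 1     (Intercept)  1.596679 0.415698  3.84 0.000329
#> 2       local_auc  0.000763 0.000275  2.78 0.007579
#> 3 education_years -0.059429 0.019623 -3.03 0.003791
```

Reading the reduced model: stronger local DLPFC reactivity before the
stress period predicts a *worse* mental-health outcome (t = 2.78 on the
Box-Cox transformed mean pandemic PHQ-4), more education a *better* one
(t = −3.03); the likelihood-ratio test (χ²(6), p = 0.08) shows the six
extra predictors of the full model add nothing, and each of the two
retained predictors explains roughly 13% of the outcome variance.

A file-based run of the whole chain — simulate to disk, score, classify,
four cluster tests, regression report, manifest with checksums — is
`run_pipeline(cfg, out_dir, seed)`; a command-line front end with
`simulate` / `score` / `cluster-test` / `regress` / `run-all` subcommands
is installed at `inst/cli/tepflow.R`.

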