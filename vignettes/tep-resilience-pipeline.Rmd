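---
title: "Evoked reactivity to TMS as a predictor of stress resilience: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evoked reactivity to TMS as a predictor of stress resilience: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepflow)
```

## The scientific problem

A single TMS pulse delivered over cortex acts as a brief, controlled
perturbation; the EEG response it evokes (the TMS-evoked potential, TEP)
indexes how the stimulated circuit absorbs and dissipates an external
insult. `tepflow` implements a complete analysis chain for the hypothesis
that this perturbation response — recorded before a period of sustained
psychosocial stress — predicts who will go on to develop mental-health
symptoms ("vulnerable") and who will not ("resilient").

The chain has five stages:

1. **Reactivity scoring** — reduce each subject's evoked response at a
   stimulation target (experimental: left DLPFC; control: left IPL) to
   per-timepoint series and scalar predictors.
2. **Classification** — label subjects resilient or vulnerable from their
   longitudinal PHQ-4 anxiety/depression trajectories.
3. **Group comparison** — compare the groups' evoked time-series pointwise
   with a permutation test, correcting for multiple comparisons by cluster
   size and magnitude.
4. **Prediction** — regress the pandemic-period mental-health score on the
   reactivity predictors and demographics, with a Box-Cox transformed
   response, nested-model comparison and variance decomposition.
5. **Synthesis** — a generator that produces cohorts with the statistical
   structure the analysis assumes, so every stage is testable end to end
   without human data.

## Reactivity measures

**Global response.** The global mean field amplitude at sample $t$ over $N$
channels $V_i$ is

$$\mathrm{GMFA}(t) = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}\big(V_i(t) - \bar V(t)\big)^2},$$

the instantaneous population standard deviation across the montage — a
reference-free summary of global evoked strength. We use the $1/N$
(population) denominator, the convention of the classical global field
power; `gmfa(..., sample_sd = TRUE)` gives the $1/(N-1)$ variant.

**Local response.** Source-space series for the ~100 vertices in the
stimulated region of interest are rectified (absolute value, per vertex),
averaged across vertices into $s(t)$, and z-scored against the pre-stimulus
baseline:

$$z(t) = \frac{s(t) - \mu}{\sigma},$$

with $\mu$, $\sigma$ the mean and population standard deviation of $s$ over
$[-500, -3]$ ms. Rectification precedes averaging, so dipoles of opposite
orientation do not cancel. A constant baseline ($\sigma = 0$) is refused
explicitly rather than producing infinities.

**Scalar predictors.** Both series are integrated by the trapezoidal rule
over the closed window $[15, 400]$ ms (units $z\cdot$ms and
$\mu V\cdot$ms). Integration starts at 15 ms because the first samples
after the pulse are dominated by the electrical artifact and are
interpolated in real recordings; the synthetic data are clean there, but
the window convention is kept identical. The pre-TMS control predictor
(`baseline_activity`) is the same trapezoidal integral of the rectified
ROI mean over the z-scoring baseline window $[-500, -3]$ ms, *before* any
z-scoring — the z-scored baseline would integrate to approximately zero by
construction. No published definition of this control quantity exists, so
this choice is the package's own, made for symmetry with the response AUC.

All windows are closed intervals including both endpoint samples, with
sample $i$ at $t_0 + (i-1) \cdot 1000/f_s$ ms.

## Classification and correlation

A subject is *resilient* iff every pandemic PHQ-4 total is $\le$ the
pre-pandemic total, *vulnerable* iff any timepoint exceeds it; subjects are
classified on however many pandemic timepoints they completed (1–3), since
restricting to complete trajectories would discard a third of a typical
cohort. The pandemic mental-health score used in the regressions is the
arithmetic mean of the completed pandemic totals. Rank correlations
(`spearman_test`) use average ranks for ties and a two-sided
t-approximation on $n-2$ degrees of freedom.

## The cluster permutation test

Pointwise two-sample tests at 1 kHz over a 386-sample window require
multiple-comparison control that respects the strong temporal
autocorrelation of evoked series; cluster correction is the standard
answer. Our construction:

* Observed statistic: $d(t) = \bar x_A(t) - \bar x_B(t)$.
* $B$ label scramblings (default 1000) give permutation differences
  $d_b(t)$; the pointwise two-sided p-value is
  $(\#\{b : |d_b(t)| \ge |d(t)|\} + 1)/(B + 1)$. The add-one correction
  avoids exact zeros; tests are two-sided because the direction of any
  group difference is a finding, not an assumption.
* Clusters are maximal runs of contiguous samples with $p(t) < \alpha$
  (no gap tolerance). Cluster *size* is the number of samples, *magnitude*
  is the mass $\sum |d(t)|$ over the run.
* The null distribution applies the identical clustering to each
  permutation's own pointwise p-values, ranked within the full ensemble.
  By default each permutation contributes its maximum cluster size and
  maximum magnitude (`null_mode = "max_per_perm"`), the standard
  construction that controls family-wise error; `null_mode = "pooled"`
  instead pools every null cluster, a laxer reading some descriptions of
  the method suggest. A cluster survives only if its size exceeds the 95th
  percentile of the null sizes *and* its magnitude exceeds the 95th
  percentile of the null magnitudes — the conjunctive reading of
  "size and magnitude above 95%".
* For groups small enough to enumerate, `exact = TRUE` replaces Monte-Carlo
  sampling with all $\binom{n}{n_A}$ assignments; pointwise p-values are
  then exact proportions. This mode is also the oracle against which the
  Monte-Carlo path is tested.

Numerical detail: permutation statistics are rounded to 12 significant
digits before rank comparisons so that algebraically identical assignments
reached by different summation orders count as exact ties; real differences
between distinct assignments are many orders of magnitude larger.

## Regression stage

Four models share the Box-Cox transformed mean pandemic PHQ-4 as response:

| model | predictors |
|---|---|
| `full_dlpfc` | local & global DLPFC AUC, both × targeting method, age, gender, education years, months since TMS (8) |
| `reduced_dlpfc` | local DLPFC AUC, education years (2) |
| `full_ipl` | the full set with IPL reactivity (8) |
| `reduced_plus_baseline` | reduced + pre-TMS baseline activity (3) |

Gender is coded female = 0 / male = 1 and targeting method anatomical = 0 /
functional = 1; the method enters only through its interactions with the
reactivity AUCs, since the reactivity × method interaction — not method
itself — is the confound of interest. The reduced DLPFC model is refitted
on exactly the full model's subjects so the likelihood-ratio test compares
nested models on one response vector.

The Box-Cox exponent is estimated per model by profile likelihood on a grid
over $[-5, 5]$ with step $10^{-3}$ (`boxcox_fit`), with an automatic shift
of $1 - \min(y)$ when the response contains zeros (a mean PHQ-4 of 0 is
common in healthy cohorts). OLS fits report per-coefficient t statistics,
the overall F test, adjusted $R^2$, and AIC/BIC computed from the full
Gaussian log-likelihood with the error variance counted as a parameter —
the convention of standard statistical packages, which matters when
comparing printed information criteria. The LRT uses
$\chi^2 = 2\Delta\ell = n\ln(\mathrm{RSS}_r/\mathrm{RSS}_f)$ on
$k_f - k_r$ degrees of freedom.

Residual normality uses a Lilliefors test: the KS statistic against a
normal with estimated parameters, with a seeded Monte-Carlo null (default
$10^4$ samples) rather than asymptotic tables, which are not valid for the
composite null. Variance decomposition is sequential (Type-I): predictors
enter in model order (reactivity before education), each percentage is the
RSS decrement over the total sum of squares, and the residual completes to
100. A partial (Type-II/III) decomposition would be equally defensible;
sequential is the default of the R `anova` family this report mirrors, and
the package exposes the order argument so the sensitivity is one call away.
Assumption diagnostics are variance inflation factors, the Durbin-Watson
statistic, and the Breusch-Pagan test — the standard trio for
multicollinearity, autocorrelation and heteroscedasticity.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: its
defaults define the conditions under which the pipeline's statistical
properties are demonstrated.

**Evoked series.** Each subject-average response is a sum of Gaussian
bumps at 30, 45, 60, 100, 185 and 230 ms (widths 6–28 ms SD, amplitudes
2–3 µV, alternating polarity — the canonical sequence of early, middle and
late TEP components, the last near the well-known ~180–230 ms late
component), projected onto source vertices and a sinusoidal sensor
topography, plus AR(1)-filtered Gaussian noise (coefficient 0.95, marginal
SD 2 µV, interpreted as the residual of a ~120-trial average; a 200-sample
warm-up makes the process stationary from the first retained sample).
Subject-average series are generated directly — a trial loop would add cost
without testing anything the averaged analysis consumes. AR(1) noise is
deliberately minimal colouring: enough temporal dependence to make
pointwise tests non-independent, which is precisely what cluster
correction exists to handle.

**Between-subject structure.** Each subject carries a standard-normal
latent vulnerability and a lognormal amplitude gain (CV 0.2) applied to all
components; without such gain variability the group test would be
unrealistically powerful and the reactivity predictors nearly degenerate
across subjects. For DLPFC stimulation only, and only on DLPFC ROI
vertices, the late (230 ms) component amplitude is multiplied by
$1 + \text{effect\_size} \times \text{vulnerability}$; the IPL target and
the sensor projection carry no vulnerability dependence, mirroring a
local-only, experimental-target-only effect.

**Questionnaires.** Pre-pandemic PHQ-4 totals are Binomial(12, 0.15)
(mean ≈ 1.8 — a healthy cohort); each completed pandemic timepoint adds
`round(1.2·vulnerability − 0.15·(education − mean) − 0.3 + N(0,1))`,
clipped to 0–12. Subscale totals are a binomial split so the PHQ-2/GAD-2
screening rule is exercisable. PSS-14 is a linear function of the mean
pandemic PHQ-4 plus Gaussian noise. Completion design: 69/23/8% of
subjects complete 3/2/1 pandemic questionnaires; 76% complete the DLPFC
target, 74% IPL, 50% both (exact counts, randomly assigned).
Demographics: age ~ rounded N(55, 7.1) truncated to 42–66, education
~ rounded N(18, 3.85) truncated to 8–28, 34/74 female, 29/74 anatomically
targeted, 1–20 months between TMS and follow-up.

**Calibrated defaults.** Three generator constants were fixed once, by
simulation, as design targets — and then left alone:

* `pss_noise_sd = 3.7`, so the median Spearman correlation between PSS-14
  and mean pandemic PHQ-4 is ≈ 0.69 at large n — the strength of the
  stress–mental-health coupling the cohort is meant to exhibit;
* `phq_intercept = -0.3`, so the resilient:vulnerable split is ≈ 1:1;
* `effect_size = 0.4`, so the standardized group difference (Cohen's d) of
  the late-window local z-response between emergent groups is ≈ 1 — a
  strong but not overwhelming neurophysiological signature.

Ground-truth labels are *not* drawn: they emerge by applying the
classification rule to the generated trajectories, so classification and
group comparison are tested jointly, including the misclassification noise
a real cohort would have.

**What the generator does not emulate.** No volume conduction or realistic
forward model (sensor topographies are synthetic sinusoids), no artifacts
(blinks, muscle, pulse), no trial-level variability, no 1/f spectral shape
beyond AR(1), and no item-level questionnaire psychometrics. Passing tests
therefore demonstrate the statistical machinery — error control,
calibration, recovery — under a plausible data-generating process, not the
preprocessing robustness or effect sizes of real recordings.

## Problem sizes used in validation

The test suite demonstrates: family-wise error control of the cluster test
on 500 null datasets (12 vs 12 subjects, 200 permutations each); effect
recovery on 100 cohorts of 74 subjects at the default effect size
(surviving DLPFC cluster with midpoint inside the injected 202–269 ms
window in ≥ 80%, surviving IPL clusters in ≤ 5%); agreement of Monte-Carlo
pointwise p-values with exhaustive enumeration for 4 vs 4 subjects at
$10^5$ permutations; OLS/LRT equality with normal-equations oracles at
$10^{-8}$; χ² calibration of the LRT under a simulated null (500
replicates, n = 200); Box-Cox recovery of identity and log transforms at
n = 500; and reduced-model coefficient sign recovery in ≥ 90% of 100
cohorts. Simulation-heavy studies use a spatially reduced profile (epoch
−1000..500 ms, 10–25 ROI vertices, 16 channels) — the criteria constrain
subjects, permutations and α, and the spatial scale affects only runtime —
while the acceptance script runs the full study-scale configuration
(−1000..2000 ms, 100-vertex ROIs, 64 channels, 74 subjects, 1000
permutations).

## Known limitations

* The cluster null can be built per-permutation-maximum (default, FWER
  controlling) or pooled; published descriptions of the correction are
  often ambiguous between the two, and pooled is laxer. Both are exposed.
* The "baseline pre-TMS activity" predictor has no canonical definition;
  ours is one reasonable choice (rectified-mean AUC over the z-scoring
  baseline window).
* Sequential ANOVA percentages depend on predictor order whenever
  predictors are correlated; order is an explicit argument.
* The Monte-Carlo Lilliefors p-value has simulation noise
  O($1/\sqrt{\text{nsim}}$); raise `nsim` for borderline decisions.
* Subjects missing required regression fields are dropped, not imputed.
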