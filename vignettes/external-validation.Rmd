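---
title: "Externally validating a survival prognostic model under heavy missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Externally validating a survival prognostic model under heavy missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(survalid)
library(dplyr)
```

## The problem

A nomogram-based prognostic model developed in Wenzhou, China predicts the
survival of people living with HIV/AIDS (PLWHA) after the start of
antiretroviral therapy (ART) from three baseline laboratory predictors: CD4
cell count, hemoglobin, and HIV viral-load category. Like any clinical
prediction model, it is only useful if its performance holds up in patients
it was not developed on. `survalid` implements the complete external
validation workflow for this model — and, because the model's development
used a matched nested case–control design, a pair of simulation experiments
that reproduce the methodological consequences of that design on synthetic
cohorts with known truth.

## The model

The model is a proportional-hazards model reconstructed from its published
nomogram. For patient $i$, the prognostic index (linear predictor) is

$$\mathrm{PI}_i = -0.005580907\,\mathrm{CD4}_i - 0.005368102\,\mathrm{Hb}_i
 + 1.019669556\,[\mathrm{VL} \in [200, 1000)) + 2.608969326\,[\mathrm{VL} \ge 1000]$$

with CD4 in cells/µL, hemoglobin in g/L and viral load in copies/mL, and
the predicted survival at $t$ years after ART initiation is

$$\hat S_i(t) = \hat S_0(t)^{\exp(\mathrm{PI}_i)},\qquad
\hat S_0(1) = 0.980222074,\ \hat S_0(2) = 0.972736744,\ \hat S_0(3) = 0.964896148.$$

The nomogram's point scale is an affine map of the prognostic index,
$\mathrm{score}_i = 108.3333333 + 19.90914787\,\mathrm{PI}_i$, and an
*extended* variant adds literature-based age-band and gender terms
($+0.2382292$ for age 40–59, $+0.5866749$ for age $\ge 60$, $-0.3566749$
for female). All coefficients are stored at full published precision and no
rounding happens inside computations.

```{r}
params <- wenzhou_params()
risk_score(0, params)
predict_survival(0, 3, params)
```

Three conventions are deliberate, because the published inequalities are
ambiguous at the boundaries: viral-load categories are half-open
($[0,200)$, $[200,1000)$, $[1000,\infty)$, so exactly 1000 copies/mL is
"high"), age bands are half-open ($[40,60)$, $[60,\infty)$), and risk-group
cutoffs have *no default* — the development study's thresholds were not
published, so `assign_risk_group()` fails fast unless cutoffs are supplied
explicitly. Absolute predictions are restricted to horizons with a
published baseline survival (1, 2, 3 years); rank-based metrics need only
the prognostic index and work at any horizon.

## Validation metrics

All performance statistics are implemented from first principles in this
package; `survival` is used for Cox model *fitting* only (and, in the test
suite, as an independent cross-check of the estimators).

* **Kaplan–Meier / Nelson–Aalen** (`km_estimate()`, `nelson_aalen()`):
  product-limit survival and cumulative hazard over distinct event times,
  with right-continuous step lookup (`surv_at()`, `cumhaz_at()`).
* **Follow-up** (`median_followup()`): reverse Kaplan–Meier — censoring
  becomes the event, and the median/IQR are read off where the curve
  crosses 0.5/0.75/0.25. Degenerate samples (curve never reaches the
  level) are flagged rather than silently extrapolated.
* **Harrell's C** (`harrell_c()`): over usable pairs (the shorter observed
  time has an event; tied times with exactly one event treat the event as
  failing first; tied times with two events are unusable), the fraction
  where the worse score fails first, score ties counting 1/2. The paper
  this workflow follows reports confidence intervals without naming a
  variance estimator, so the standard error comes from a seeded
  nonparametric bootstrap (default 200 replicates, percentile interval).
* **Time-dependent C** (`timedep_c()`): IPCW truncated concordance at a
  horizon $t$ — cases are events by $t$, comparators are subjects still at
  risk at $t$, case weights $1/\hat G(X_i^-)$ from the censoring
  Kaplan–Meier. The defining property (pinned in tests): with no censoring
  before $t$ it reduces exactly to the unweighted truncated concordance.
  Several estimator variants exist in the literature; this definition is a
  documented package choice.
* **Calibration** (`calibration_table()`): subjects are binned by deciles
  of predicted survival (default 10 quantile bins), and per bin the mean
  prediction is compared with the Kaplan–Meier observed survival at the
  horizon. The difference is always **observed − predicted**: positive
  means the model underestimates survival (overestimates mortality). Both
  the bin-average and the patient-weighted average are reported;
  bin-average is the headline number. Bins with no subject at risk at the
  horizon are flagged.
* **Rates** (`poisson_rate_ci()`): exact Poisson intervals from chi-square
  quantiles, the convention that reproduces published registry rates.

```{r}
poisson_rate_ci(743, 65037)
```

* **Rubin pooling** (`pool_rubin()`): pooled mean, total variance
  `within + (1 + 1/m) between`, t reference with Barnard–Rubin degrees of
  freedom. C-statistics are pooled on the logit scale (delta-method
  variances, back-transformed interval) because they are bounded.

## Missing data

The registry this workflow targets is missing the viral-load predictor for
~86% of patients, so the main analysis runs on multiply imputed data.
`chained_imputation()` implements chained equations directly:

* continuous variables: Bayesian linear-regression parameter draw followed
  by type-1 predictive-mean matching with a donor pool of 5 (common
  practice; the source analysis does not state these settings);
* categorical variables: multinomial regression fitted on observed rows,
  then a category draw from the predicted probabilities;
* the outcome enters the imputation model as the Nelson–Aalen cumulative
  hazard at each subject's follow-up time plus the event indicator, the
  standard representation for censored outcomes;
* laboratory values are log-transformed first (`log_transform_labs()`,
  exactly invertible), since labs are positive and right-skewed;
* defaults: `m = 50` imputations and 10 chained iterations (`m` follows
  the source analysis; the iteration count is a package choice).

Observed values are never altered (asserted cell-wise in tests), constant
or incomplete non-imputed predictors are dropped with a notice, and the
whole procedure is reproducible from a single seed. Viral load is imputed
on the categorical scale directly, since that is how the registry records
it. Two sensitivity scenarios bracket the imputation assumptions:
`scenario_vl_all_low()` (every missing viral load < 200 copies/mL) and
`scenario_vl_reference()` (missing values drawn from the derivation
cohort's published distribution, 78.7/3.0/18.3%).

## The synthetic cohort generator

The registry itself is not publicly available, so `simulate_cohort()`
generates cohorts that emulate its published profile, with per-record truth
retained for oracle checks. What the defaults emulate:

* CD4 and hemoglobin log-normal, moment-matched to the published medians
  and IQRs (CD4 209, 72–319 cells/µL; Hb 137, 116–150 g/L): `meanlog` is
  the log median and `sdlog` is the log-IQR width divided by
  $2\,\Phi^{-1}(0.75)$. A log-normal cannot match an asymmetric IQR
  exactly; the median is matched exactly and the spread approximately.
* Viral-load categories at the observed validation-cohort mix
  (1.6/2.4/96.0%); age log-normal (median 34.3, IQR 27.2–44.0) truncated
  below 16 years; 81.5% male.
* Event times from the proportional-hazards model with the published
  coefficients as the generating truth and a Weibull baseline with shape
  0.75 — a declining hazard after ART start — whose scale (652.9857) was
  calibrated once, by solving for the population 3-year cumulative
  mortality of 3.72%, and then frozen.
* Censoring from the enrolment process: entry drawn over the four
  published calendar eras (3.4/13.3/34.7/48.6%), administrative cut-off at
  the assessment date, plus a small exponential dropout hazard
  (0.01/year — the registry's true dropout process is unobservable, so
  this is a free parameter held at a plausibly small value).

Under these defaults a large cohort realises a mortality rate of ~10.8 per
1000 person-years (the published 11.4 within 6%) and a median follow-up
near 3.9 years (published 3.41). What the generator does **not** emulate:
measurement error and digit preference in labs, competing risks,
calendar-period improvements in care, within-patient follow-up dynamics,
and the correlation structure of the full 26-variable auxiliary panel
(only four auxiliary labs, correlated with CD4, are generated). Passing
tests on synthetic cohorts therefore validate the *methods* — estimator
correctness, pipeline plumbing, direction and mechanism of the biases —
not the real-data performance numbers, which depend on the non-public
registry.

`impose_missingness()` masks viral load under a missing-at-random
mechanism driven by enrolment year (earlier entry, more missingness,
emulating limited early viral-load testing), with the logistic intercept
solved so the expected missing fraction hits the target.

## Simulation experiments

Two experiments replay the development study's methodological problems on
cohorts where the truth is known.

**Case–control calibration bias** (`experiment_case_control_bias()`). The
development study fixed its event fraction at 20% by sampling one death
plus four matched survivors. Fitting a standard Cox model to such a sample
as if it were a cohort inflates the Breslow baseline hazard roughly
five-fold, so every predicted survival is too low even though the
coefficients are nearly unbiased. The experiment develops a model on (a) a
1:4 age/gender-matched nested case–control subsample and (b) a random
subcohort of identical size, then validates both on an independent
population cohort: arm (a) shows a clearly positive mean
(observed − predicted) survival difference, arm (b) centres at zero.

**Added value of matched-away predictors**
(`experiment_added_value()`). Matching on age and gender removes them from
the candidate predictor set. Generating cohorts in which age and gender
carry their literature effect sizes and scoring with and without the
extension shows the discrimination cost: the extended model's Harrell's C
exceeds the original's.

## Numerical and design choices

* Seeds: every stochastic function takes an explicit integer seed;
  `NULL` leaves the RNG stream untouched. Identical seeds give
  byte-identical results (imputation, bootstrap, sampling, generation).
* Bootstrap percentile intervals are clamped to bracket the point
  estimate (they are not guaranteed to otherwise).
* The score mapping is exactly invertible; `index_from_score()` recovers
  the prognostic index to 1e−9, which the tests assert.
* Ties: Breslow handling in Cox fits; the concordance tie conventions
  above.
* Problem sizes in the test suite: estimator oracles run at n ≤ 50 with
  exhaustive enumeration; parameter recovery at n = 20 000; calibration
  self-consistency at n = 10 000; the bias and added-value experiments at
  development/validation sizes of 5 000/8 000 and 20 000 over five seeds;
  the imputation workflow at n = 2 000 with m = 10. These sizes keep
  Monte-Carlo error comfortably inside the assertion bands.
* `recovery_config()` is a deliberately well-conditioned design for
  coefficient-recovery checks (balanced viral-load mix, wider hemoglobin
  spread, exponential baseline rate 0.15, no dropout). Under the
  registry-emulating defaults the hemoglobin coefficient is weakly
  identified — a small effect times a narrow spread — and no n = 20 000
  design with those margins can pin it to 10% relative error; recovery is
  a property of the fitter, so it is checked where the design carries
  adequate information.

## Worked pipeline run

```{r, message = FALSE}
cfg <- cohort_config(n = 2000)
cohort <- simulate_cohort(cfg, seed = 1) |>
  impose_missingness(target = 0.5, seed = 2)
report <- run_validation(cohort, generator_model_params(cfg),
                         m = 5, seed = 3, horizons_td = c(1, 3, 5),
                         boot = 50)
report
```

Because the scoring model here *is* the generating model, the calibration
differences sit at zero up to Monte-Carlo error and the pooled C matches
the complete-data C — the pipeline's self-consistency oracle. Validating
the Wenzhou parameters against cohorts they did not generate is the same
call with `params = wenzhou_params()`.

## Known limitations

* Risk-group counts require user-supplied cutoffs (not published).
* Absolute-risk predictions exist only at 1/2/3 years.
* No competing-risks estimators: the workflow validates the model as
  published; a development-side fix (Fine–Gray) is out of scope.
* The time-dependent C pooled across imputations is reported as the
  across-imputation mean without an interval; the overall C carries the
  full Rubin interval.
* Synthetic cohorts support method-level conclusions only, as described
  above.
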