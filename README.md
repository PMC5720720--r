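# ckdmsm

Antiretroviral therapy (ART) keeps people with HIV alive for decades, but
some regimens stress the kidneys. Tenofovir disoproxil fumarate (TDF) is the
classic example, and the suspicion is that TDF combined with a
ritonavir-boosted protease inhibitor (rbPI) carries a higher risk of chronic
kidney disease (CKD, a confirmed eGFR below 60 ml/min/1.73m²) than TDF with
an NNRTI. Estimating that effect from observational cohorts is hard for one
specific reason: when a patient's eGFR starts falling, clinicians switch
them *away* from TDF. Current renal function is therefore a **time-varying
confounder affected by prior treatment** — it predicts both future regimen
changes and the outcome — and standard Cox regression cannot adjust for it
without blocking part of the effect.

`ckdmsm` implements, as a reusable and tested pipeline, the full comparison
of analysis strategies for this problem:

* **data preparation** — MDRD eGFR from serum creatinine
  (175 · Scr⁻¹·¹⁵⁴ · age⁻⁰·²⁰³ · 0.742 if female), eligibility screening,
  five-category regimen classification (TDF±/rbPI, TDF±/NNRTI, other),
  confirmed-CKD detection (two sub-60 values ≥ 90 days apart), and
  expansion into consecutive 30.44-day person-months with
  last-value-carried-forward covariate categories;
* **traditional Cox models** for all CKD events under three exposure
  codings (initial regimen, current regimen, current + previous regimen),
  fitted on counting-process person-month data with Efron ties;
* **a marginal structural Cox model**: patients censored at any regimen
  change, re-weighted by stabilized inverse-probability-of-treatment-and-
  censoring weights
  SW(t) = sw\_A · Π<sub>k≤t</sub> (num<sub>k</sub>/den<sub>k</sub>),
  where sw\_A comes from a polytomous logistic model of the initial regimen
  on baseline confounders and the monthly switch/censor probabilities come
  from pooled logistic models with 3-knot restricted-cubic-spline time
  intercepts and step-function time-varying CD4 / viral-load / eGFR
  categories;
* **a doubly robust estimator** (the weighted fit with the full covariate
  set) and patient-clustered sandwich variances throughout;
* **negative-binomial models** of regimen discontinuation rates by current
  eGFR category — the diagnostic that shows the treatment–confounder
  feedback directly;
* **a synthetic cohort generator** (`sim_config()`, `simulate_cohort()`)
  that reproduces the statistical structure this analysis assumes —
  regimen-dependent eGFR drift, eGFR-dependent switching, sparse laboratory
  sampling (median gap ≈ 2.6 months), realistic baseline marginals, a CKD
  incidence of order 9.6/1000 person-years — plus a counterfactual oracle
  mode (`simulate_counterfactual_reference()`) that returns the true
  marginal hazard ratios, so estimator bias and coverage can be measured.

## Worked example

```r
library(ckdmsm)

cfg    <- sim_scenario("cohort", n_patients = 3000, seed = 42)
report <- run_pipeline(cfg)
report
#> ckdmsm pipeline report
#>   eligible patients: 2955, events: 99, person-months: 128527
#>   CKD incidence: 9.2 /1000 PY overall (95% CI 7.5-11.3), 7.9 on initial regimen
#> Stabilized weights: n = 78726, mean = 1.004 (SD 0.421), range 0.133-12.669
#>   crude         TDF+/rbPI vs TDF+/NNRTI: HR 1.61 (0.75-3.46)
#>   adjusted      TDF+/rbPI vs TDF+/NNRTI: HR 1.45 (0.66-3.19)
#>   weighted      TDF+/rbPI vs TDF+/NNRTI: HR 1.69 (0.73-3.92)
#>   doubly_robust TDF+/rbPI vs TDF+/NNRTI: HR 1.64 (0.70-3.84)
```

Reading this: the simulated cohort lands near the calibration targets
(incidence just above 9/1000 person-years; stabilized weights centred at 1
with a narrow spread, as they should be when the weight models are
correctly specified). The four hazard-ratio blocks mirror the standard
reporting layout for this analysis: an unadjusted on-initial-regimen model,
a covariate-adjusted one, the weighted marginal structural model, and the
doubly robust estimator.

The stages are also available individually and pipe together:

```r
sim  <- simulate_cohort(cfg)
prep <- prepare_cohort(sim$patients, sim$labs, sim$regimens)
wts  <- estimate_weights(prep$person_months)
fit  <- fit_msm(prep$person_months, weights = wts$weights, estimator = "weighted")
tidy(fit)          # broom-style coefficient table
glance(fit)        # one-row fit summary
autoplot(wts$diagnostics)   # SW(t) over follow-up
```

For estimator validation, `run_estimator_replicates()` +
`compare_estimators()` run the whole pipeline over replicated cohorts and
score bias, RMSE and CI coverage against the counterfactual oracle.

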