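---
title: "Marginal structural Cox models for ART regimens and chronic kidney disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural Cox models for ART regimens and chronic kidney disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the design
decisions taken where more than one defensible choice existed.

## The estimation problem

We want the effect of the *initial* antiretroviral regimen type — tenofovir
(TDF) with a boosted PI, TDF with an NNRTI, the same backbones without TDF,
or anything else — on the hazard of chronic kidney disease, defined as a
confirmed (two values at least 90 days apart) eGFR below 60 ml/min/1.73m².
The obstacle is treatment–confounder feedback: declining eGFR raises both
the CKD hazard and the probability that the clinician switches the patient
off TDF. Censoring follow-up at the switch (the natural way to isolate the
initial regimen's effect) is therefore *informative*: the patients who
remain on a nephrotoxic regimen are selected for good kidneys, and a naive
on-treatment Cox model understates or distorts the effect. Conditioning on
current eGFR instead would block part of the causal pathway, since eGFR is
also a mediator of the regimen's effect.

The marginal structural model resolves this by re-weighting instead of
conditioning. Follow-up is cut into consecutive 30.44-day person-months.
Each on-initial person-month receives a stabilized weight

$$SW(t) \;=\; sw_A \times \prod_{k \le t}
  \frac{P(\text{unswitched at }k \mid \text{baseline, stabilizers})\;
        P(\text{uncensored at }k \mid \cdot)}
       {P(\text{unswitched at }k \mid \text{baseline, time-varying history})\;
        P(\text{uncensored at }k \mid \cdot)},$$

where $sw_A$ is the marginal frequency of the patient's observed initial
type divided by its polytomous-logistic probability given baseline
covariates. In the weighted pseudo-population, switching and loss to
follow-up are unrelated to the measured history, so a covariate-free
weighted Cox fit on the initial-type indicators estimates the marginal
("randomized-trial") effect of staying on each regimen, under the usual
assumptions: no unmeasured confounding of switching/censoring given the
measured history, positivity, and correctly specified weight models.

Four estimators are fitted on the same on-initial person-month data
(`fit_msm()`): crude, covariate-adjusted, SW(t)-weighted, and doubly robust
(weighted *and* adjusted; consistent if either the weight models or the
outcome model are right). All use Efron ties on the counting-process rows
and patient-clustered sandwich variances — the variance choice is ours (the
approach's standard), since weighted partial likelihoods make model-based
variances invalid. Weights are normalised to mean one before fitting; point
estimates are invariant to positive rescaling, and a test asserts this.

The traditional analysis series (`fit_cox()`) uses *all* CKD events with
three exposure codings — initial type, current type, and current plus
previous type — adjusted for the baseline set and time-varying CD4 and
viral-load categories. Continuous baseline confounders enter linearly by
default (a restricted-cubic-spline option exists); the published analyses
this mirrors explored several codings without fixing one, and the linear
form is the most transparent default.

## Weight models

The switch and censoring hazards are estimated by pooled logistic
regressions on the on-initial person-months. The denominator model carries:
a restricted cubic spline in month since entry (3 knots at the 10th/50th/
90th percentiles of the realized distribution — recomputed per dataset),
3-knot splines of the continuous baseline covariates (age, nadir CD4,
baseline CD4, log10 viral load, baseline eGFR), calendar year linearly,
sex, HIV exposure group, the comorbidity flags, and step functions of the
time-varying CD4 (≤200 / 201–350 / >350), viral load (≤50 / 51–500 / >500)
and eGFR (≤50 / 51–70 / 71–90 / >90) categories. The spline basis is
Harrell's truncated-power form, implemented directly and tested against a
brute-force evaluation; it is linear beyond the boundary knots.

Three design decisions deserve explanation:

* **Stratification.** By default the four models are fitted separately for
  TDF-containing and TDF-free initial regimens, with initial-type main
  effects inside each stratum (`stratify = "tdf"`). Switching behaviour
  differs mainly by TDF exposure, and two strata keep each model's events
  numerous relative to its ~30 parameters. Fully type-specific fits
  (`"regimen"`) are available, but five 30-parameter models per outcome on
  a moderate cohort overfit, and weight-model overfitting is not benign: the
  estimation noise enters SW(t) *multiplicatively* month after month,
  inflating the weight tails and median-biasing the weighted estimator. A
  pooled option (`"none"`) and an automatic pooled fallback for strata with
  fewer than 5 switch events complete the set.
* **Numerator content.** `numerator = "baseline"` (default) gives the
  numerator models the same time spline and baseline-covariate terms as the
  denominators, omitting only the time-varying categories; this is the
  classical stabilization that keeps SW(t) tightly centred at 1. Strictly,
  stabilizing on baseline covariates is guaranteed bias-free only when the
  outcome model adjusts for them (as the doubly robust estimator does);
  for the covariate-free weighted fit it is an approximation that is exact
  when switching and censoring depend on baseline covariates only weakly —
  true in every scenario shipped here, and verified empirically at large n
  in the test suite. `numerator = "time"` (time spline only) is the
  strictly marginal-safe alternative; its cumulative ratios drift over long
  follow-up, so the weight distribution is wider.
* **What counts as censoring.** Only loss to follow-up is modelled by the
  censoring weights. Administrative end of follow-up (database close,
  2013-12-31 by default) is deterministic given the entry date and
  non-informative by design; modelling it as an outcome would make the
  censoring models chase a near-certain "event" at an entry-dependent
  horizon, which destabilises the weights for no identification gain.

Fitted treatment probabilities are floored at 1e-6 (with a warning) before
ratio formation, so separation cannot produce infinite weights. Weight
truncation is off by default — the weight distribution itself is a
diagnostic (`weight_diagnostics()`, `autoplot()`), and symmetric percentile
truncation is available where needed.

## The synthetic cohort generator

No patient-level data from this kind of national HIV cohort are public, so
the generator (`sim_config()`, `simulate_cohort()`) produces cohorts with
the statistical structure the analysis assumes, calibrated to the published
margins of a large French cohort starting first-line ART in 2004–2012:
median age 39, baseline eGFR median 101 (IQR ≈ 86–118), CD4 median 289,
viral load median 4.8 log10, 73% male, initial-type shares 19/37/5/25/14%,
creatinine measurements at log-normally spaced visits with a median gap of
2.6 months (capped at 12, with guaranteed month-1/month-2 visits and a
pre-ART baseline draw), roughly half the patients still on their initial
type after a median ~3 years, and a confirmed-CKD incidence of order
9.6 per 1000 person-years under the `"cohort"` scenario.

Mechanics, month by month: latent eGFR follows a random walk with
regimen-dependent drift (ml/min/1.73m² per month) and innovation SD 2,
reflected just above 60 so that the *only* event pathway is the explicit
discrete-time hazard
$\exp(\beta_0 + \log HR_{\text{regimen}} + \gamma_{\text{eGFR cat}}
+ \text{baseline frailty})$ —
this keeps "the true effect" a model parameter rather than an emergent
property of the walk, which is what makes parameter recovery well-posed.
Switching follows a logistic model in the last *observed* (laboratory,
last-value-carried-forward) eGFR category — clinicians react to measured
values, and this makes the analyst's weight models correctly specifiable
from the exported files; the destination type comes from a fixed transition
matrix that sends TDF types to their TDF-free counterpart with probability
0.6 and to "other" with 0.2. Dropout is a constant monthly hazard;
administrative censoring follows the entry date. When a hazard event fires,
the generator emits a sub-60 laboratory pair (index value in the event
month, confirmation 95 days later) and ends follow-up, so the confirmed-CKD
detector recovers the event month from the exported files alone.

Covariate marginals are truncated to clinically sensible ranges (eGFR
65–150, CD4 10–900, viral load 3–7 log10 at untreated presentation). This
matters statistically as well as clinically: assignment operates through
linear logits on standardised covariates, and bounded covariates keep every
patient's assignment probability bounded away from zero, so baseline
treatment weights cannot explode and the analyst's linear polytomous model
is exactly the generating model.

What the generator does **not** emulate: within-category drug
substitutions, mortality as a competing risk, measurement error beyond
sampling sparsity, secular calendar-time trends in prescribing, informative
(covariate-dependent) dropout. Passing tests on these cohorts therefore
show that the estimators do what they claim *under the assumed structure*;
they do not certify performance on real data where those assumptions fail.

## The counterfactual oracle

`simulate_counterfactual_reference()` defines the truth the estimators are
scored against: assignment randomised to the study's marginal shares,
switching disabled, and an unadjusted Cox fit on the true event months at
large n. Two points are easy to get wrong and are deliberate here. First,
the oracle randomises assignment — with confounded assignment an unadjusted
fit would itself be confounded, and "marginal effect" means the
randomized-trial contrast. Second, the oracle *keeps the study's censoring
schedule* (entry-dependent administrative end, and by default the
non-informative dropout process). The drift pathway makes the marginal
hazard ratio horizon-dependent — the eGFR gap between regimens accumulates
— and stabilized weights balance covariates but extend nobody's follow-up,
so the weighted analysis targets the no-switching world *under the study's
censoring*. Following everyone to the 10-year administrative maximum
instead shifts the estimand substantially; `full_followup = TRUE` exposes
that literal mode.

## Validation scenarios and problem sizes

Four named scenarios (`sim_scenario()`) fix the study conditions:

* `"cohort"` — the calibration scenario above; used for the paper-scale
  pipeline run and the weight-sanity diagnostics (n = 6301, one cohort).
* `"validation"` — same structure with a higher event rate (intercept
  raised by log 10, incidence of order 80/1000 person-years) and explicit
  channeling: immunologically healthy patients (high CD4/nadir)
  preferentially start TDF/NNRTI while older, high-viral-load patients
  start TDF/rbPI, with age and CD4 also entering the outcome hazard, plus
  mild eGFR-driven switching. The event-rate choice is a precision
  argument made before the acceptance studies were run: recovering a log
  hazard ratio to a median bias of 0.05 over 100 replicates of n = 2000
  needs a per-replicate standard error well under 0.25, i.e. hundreds of
  events per replicate, which the calibration incidence cannot supply at
  that n. The channeling design uses positive assignment boosts only:
  suppressing an arm directly creates patients with near-zero assignment
  probability (unbounded weights), while boosting *other* arms bounds every
  probability from below through the softmax normalisation.
* `"null"` — the validation scenario with all direct regimen effects zero
  and equal drifts (feedback and channeling still on): the causal null,
  used to check the size of the weighted Wald test.
* `"no_feedback"` / `"randomized"` — switching independent of eGFR and/or
  assignment independent of covariates; the degenerate limits in which all
  estimators must agree.

Monte-Carlo problem sizes used by the acceptance studies: 100 replicates of
n = 2000 (recovery and bias-ordering), 200 replicates of n = 2000 (null
size), a 50 000-patient oracle, one n = 6301 cohort for weight sanity, one
n = 8000 no-confounding cohort for estimator agreement, and n = 5000 for
the discontinuation rate-ratio recovery.

## Data-preparation conventions

Where the field's verbal definitions underdetermine an implementation, the
package fixes these readings (each is a flag or argument where reasonable):

* Months are fixed 30.44-day intervals from ART start — deterministic and
  locale-independent, unlike calendar months.
* "Within 6 months before start" is the closed interval of 180 days;
  "3 months apart" is ≥ 90 days.
* Confirmation is strict: every measurement between the index and
  confirming sub-60 values must also be below 60; a single recovery voids
  the candidate and the scan restarts after it
  (`any_later_confirm = TRUE` relaxes this).
* CD4 categories are ≤200 / 201–350 / >350: printed bounds like "199–350"
  overlap at 199–200 and cannot all be exclusive; this is the conventional
  split.
* The MDRD equation is the IDMS-traceable 4-variable form with the 175
  coefficient and no race term by default (`black = TRUE` enables the
  1.212 factor); eGFR uses age at the measurement date.
* A "switch" is a change of five-level category; substituting drugs within
  a category neither ends on-initial follow-up nor counts as
  discontinuation.
* Eligibility: start on/after 2004-01-01, baseline eGFR present and
  strictly > 60, at least two post-start creatinines; the exclusion log
  records the first failing rule.

## Numerical choices

Cox fits use Efron tie handling (the monthly grid creates heavy ties, where
Efron is markedly more accurate than Breslow). Pooled logistic models are
fitted by IRLS on prebuilt design matrices with constant columns dropped
per stratum; convergence tolerance 1e-7 (argument-controlled where exact
saturated-model agreement is being tested). The polytomous treatment model
uses `nnet::multinom` (BFGS, tight tolerance); with two observed categories
it reduces to a single logistic IRLS fit. Degenerate spline inputs
(heavily tied variables) fall back to evenly spaced knots. Exposure arms
with zero events are reported with an `infinite_se` flag rather than
dropped. "OTHER" regimen contrasts are estimated but flagged as suppressed
in reports, matching the field's reporting convention for a heterogeneous
residual category.

## Known limitations

The weighted estimator inherits the finite-sample behaviour of all
inverse-probability methods: with strong confounding the weight
distribution is right-skewed and the median replicate slightly
underestimates strong effects at moderate n. The baseline-stabilized
numerator is exactly marginal-valid only under weak baseline dependence of
switching (see above). Death is not modelled as a competing risk; the
confirmed-CKD definition ignores recovery after confirmation; and the
traditional current-regimen coding, as the comparison itself illustrates,
has no causal interpretation under feedback — reproducing that contrast is
the package's point, not a defect.
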