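---
title: "A validated Markov cohort model for heart failure with LVEF >= 40%"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A validated Markov cohort model for heart failure with LVEF >= 40%}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfmarkov)
```

## The decision problem

Finerenone, a non-steroidal mineralocorticoid receptor antagonist, reduces
cardiovascular death and total heart-failure events (hospitalisations for
heart failure, HHF, and urgent heart-failure visits, UHFV) in patients with
chronic heart failure and a left ventricular ejection fraction of 40% or
more. Health-technology assessment of such a therapy needs a lifetime
extrapolation of the within-trial effect. `hfmarkov` implements the cohort
state-transition model used for that purpose, together with the machinery
needed to *validate* it: internal property checks, a cross-validation
adjustment that re-expresses the model in a comparator model's settings, and
an external validation that confronts model projections with on-treatment
trial event counts.

Because the underlying patient-level trial data are confidential, the
package includes a synthetic trial generator with the same statistical
structure, so every stage — estimation, engine, validation — is exercised
end to end on data whose generating truth is known.

## Model structure

The cohort moves among six states in discrete cycles of 28 days over a
horizon of 28 years (366 cycles; the mean starting age of 72 makes a longer
horizon immaterial):

* four alive states defined by quartiles of the Kansas City Cardiomyopathy
  Questionnaire total summary score (KCCQ TSS), with fixed lower-closed
  bounds Q1 [1, 50), Q2 [50, 69.8), Q3 [69.8, 87.5), Q4 [87.5, 100];
* two absorbing death states, cardiovascular (CV) and non-CV.

Within a cycle, deaths are applied first to every alive state
(probabilities taken as given, not hazard-partitioned — the ordering is a
modelling choice the source material leaves open), and survivors are then
redistributed among the KCCQ states by a 4x4 row-stochastic matrix
estimated from 30-day assessment panels. The 30-day assessment interval is
mapped one-to-one onto the 28-day cycle without rescaling; the small clock
mismatch is well below the uncertainty in the transition estimates.

### Mortality

CV and all-cause death are extrapolated with parametric survival models
(exponential, Weibull, log-normal, log-logistic, Gompertz, generalised
gamma; selection by lowest AIC, with ties within 2 units resolved towards
the fewer-parameter family). Non-CV mortality is the all-cause minus the CV
probability per cycle, floored at zero, and **capped** each cycle by the
sex-weighted, cause-deleted general-population probability at the attained
integer age: `qx * (1 - cv_fraction)`, converted to the cycle length. The
cap prevents implausibly high extrapolated background mortality and the
cause deletion avoids double counting CV deaths. The packaged life table is
synthetic (Gompertz–Makeham hazards of realistic magnitude, labelled
`uk_life_table_synthetic.csv`); any national table with the same columns
can be supplied. The cohort keeps a fixed 54.5/45.5 male/female mix for
life-table lookups; the mix is not updated as differential mortality
accrues, a deliberate simplification.

### Recurrent events

Expected HHF and UHFV counts follow a marginal log-linear model (GEE-type)
in baseline age (continuous, per year), sex and race with a log-exposure
offset. Because no dedicated GEE fitter is part of this package's
dependency set and all covariates are constant within patient, the model is
fitted as a Poisson GLM on per-patient aggregated counts; for
cluster-constant covariates the marginal point estimates coincide with GEE
estimates under any working correlation. The engine evaluates the fitted
rate at the *attained* cohort age each cycle, so event risk rises as the
cohort ages — the mechanism that makes projected HHF counts sensitive to
the assumed baseline age, and the known source of HHF overestimation when a
single mean age stands in for an age distribution (the rate model is convex
in age, so the rate at the mean age understates the mean rate, while cohort
ageing pushes the other way).

### Treatment discontinuation

The active arm blends active-arm and control-arm risk sets by the fraction
of the cohort still on treatment under a discontinuation curve (log-normal
in the reference analysis, selected by lowest AIC among the six families):
patients who stop treatment carry control-arm risks thereafter. Setting the
curve to `NULL` keeps everyone on treatment; the control arm never uses it.

### Utilities, discounting, half-cycle correction

Life years and QALYs use the trapezoid of cycle-start and cycle-end
occupancy (half-cycle correction), as do reported cumulative event counts.
Per-state utilities (defaults 0.64/0.74/0.81/0.86 for Q1–Q4, plausible
magnitudes for KCCQ-quartile HF states) are adjusted by an age-related
decrement of −0.0051 per year of attained age beyond baseline, evaluated at
cycle start. Expected HF events and adverse events subtract one-off QALY
decrements (no duration convention — the usual treatment of recurrent-event
disutilities in this model family). Discounting is 3.5% per year on a
continuous clock `(1+d)^(-t)` from time zero; an `exempt_first_year`
dialect (first year undiscounted, clock shifted by one year) is available
because published comparator models differ in when discounting starts, and
neither convention can be pinned down exactly. Cross-model discounted
differences of the order of 0.1–0.2 LY can arise from this choice alone.

### Adverse events

Observed trial shares of the most frequent adverse events are spread over
cycles with a constant-risk assumption,
`p = 1 - (1 - share)^(cycle/followup)`, using a 32-month median follow-up.
The default basket (hyperkalaemia, pneumonia, atrial fibrillation, acute
kidney injury) carries small one-off disutilities and is shared between
arms — a simplification, since arm-specific AE incidence is not part of the
synthetic generator.

## The synthetic trial generator

`generate_trial()` draws, per arm: truncated-normal baseline age
(mean 72, SD 10, bounds 40–97 — the SD follows from the published age sweep
"one standard deviation" spanning 62–82, the bounds from the stated age
range), sex (54.5% male), race (78/17/2/3% White/Asian/Black/Other,
plausible for a large international HF trial), baseline KCCQ by quartile
occupancy 23.95/26.15/24.55/25.35% with uniform scores within bands,
exponential cause-specific death times (CV 2.1/2.45 per 100 person-years
active/control, non-CV 1.8 in both arms), log-normal discontinuation with a
28-month median, recurrent events from a piecewise-constant Poisson process
evaluated per 28-day cycle at the patient's attained age, and a sticky
monthly KCCQ band process. Follow-up is 29 months, mirroring the
on-treatment validation window. Event-rate magnitudes (per-cycle HHF
0.0056/0.0081 and UHFV 0.00076/0.00143 at age 72; age coefficients 0.02/yr
for HHF and 0.065/yr for UHFV) were calibrated once to the published
on-treatment event counts and the published span of the age sweep, and are
fixed defaults, not tuning knobs.

What the generator does **not** emulate: correlation between KCCQ state and
event/death risk (events and mortality are state-independent given age),
arm-specific adverse events, informative censoring, and the real trial's
covariance between age and comorbidity. Passing tests therefore demonstrate
correctness of the estimation-engine-validation chain under the stated
generating process, not fidelity of any particular parameter value to the
confidential trial.

## Validation machinery

* **Internal**: mass conservation to 1e-12 per cycle, monotone death
  states, discounted ≤ undiscounted, QALY ≤ LY under utilities ≤ 1, and
  agreement of the cohort engine with a 100,000-subject individual-level
  microsimulation within 3 Monte-Carlo standard errors.
* **Cross-validation** (`apply_cohen_settings()`): constant monthly
  mortality from rates per 100 person-years (3.56 for CV in the published
  comparison, converting to 0.0030 per month), constant event and
  discontinuation probabilities, calendar-month cycles, 3% discounting, no
  AE disutilities, and HF-event disutilities only after the first year.
  Every constant is a required input — the comparator's rates are not
  bundled, so the adapter refuses to invent them.
* **External validation** (`apply_external_validation_settings()`,
  `age_sensitivity()`, `external_validation()`): zero discontinuation
  (matching the on-treatment dataset), a 29-month window (28 months median
  time on treatment plus one reporting month, interpolated at 31.52 cycles
  on the 28-day grid), undiscounted half-cycle-corrected counts, and a
  baseline-age sweep over 62–82. Differences are reported as
  `|trial − model|` absolutely and relative to the trial arm count (arm
  rows) or the absolute trial incremental (incremental rows); that
  denominator choice reproduces every published difference cell exactly.
  Published tables may carry incremental rows computed from unrounded
  outputs; `external_validation()` therefore accepts explicit incremental
  counts that take precedence over the arm-count difference.

## Sensitivity analysis

`run_dsa()` varies one parameter at a time between deterministic bounds and
sorts the outcome swings (tornado). `run_psa()` redraws all uncertain
parameters each iteration (1000 iterations in the reference analysis; beta
for probabilities and utilities, gamma/log-normal for rates, Dirichlet for
transition rows) with one RNG substream per iteration derived from the
master seed, so results are independent of evaluation order. Summaries are
means with 2.5/97.5 percentile intervals; `summarize_psa()` applies the
external-validation difference definitions to the PSA means and flags
deviations below 20%.

## Numerical choices and degenerate inputs

* Cycle grid: `ceiling(horizon/cycle)` cycles; month = 365.25/12 days;
  year = 365.25 days.
* Rate-to-probability conversions use the constant-hazard transform
  `1 - exp(-rate * t)`, not naive division; at the published magnitude both
  round to the same monthly probability, so the printed value cannot
  discriminate between them.
* All-censored survival data raise an estimation-failure error; a
  generalised-gamma fit that fails to converge is dropped from the family
  comparison with a warning rather than aborting it.
* Transition rows with no observed moves become identity rows with a
  warning, keeping matrices row-stochastic.
* A trial with no events of a type yields a zero-rate event model flagged
  `zero_rate`, not a degenerate `-Inf` intercept fit.
* Occupancy leaks beyond 1e-9 abort the run; in practice drift stays below
  1e-13 over 366 cycles.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run the generator at 2,000–60,000
patients per arm depending on what the check needs (moment checks use the
largest sizes), the microsimulation oracle at 100,000 subjects, and the
probabilistic analysis at 60–200 iterations on the 29-month validation
configuration; these sizes give Monte-Carlo error well inside the 3-SE
acceptance bands while keeping a full run in the order of seconds. The
published trial's arm sizes are not part of the public record used here, so
trial-scale counts use 3,000 patients per arm, close to the enrolled total
of about 6,000.

## Known limitations

* Event and death risks do not depend on the KCCQ state, only on age and
  the covariate mix; utility is the only channel through which the KCCQ
  process affects outcomes.
* The sex mix is frozen at baseline for life-table lookups.
* Costs, ICERs and net monetary benefit are out of scope, as is the
  NYHA-class alternative state structure and any renal-state elaboration
  beyond the generic adverse-event channel.
* Headline trial-scale magnitudes depend on confidential parameter
  estimates; with synthetic inputs the package reproduces the *mechanisms*
  (directionality of the comparator adjustment, age monotonicity of event
  projections, sub-20% probabilistic deviations) rather than the published
  numbers.
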