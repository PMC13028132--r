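# hfmarkov

A Markov cohort model of chronic heart failure with left ventricular
ejection fraction ≥ 40%, for health-economic analysis of finerenone added
to standard of care (SoC), together with the full validation machinery such
a model needs before it can inform reimbursement decisions: internal
property checks, cross-validation against comparator-model settings, and
external validation against on-treatment trial event counts. It is aimed at
health-economic modellers and methodologists who want a fully reproducible,
testable implementation of this model family.

## The model

The cohort occupies six states: four alive states defined by quartiles of
the Kansas City Cardiomyopathy Questionnaire total summary score
(Q1 [1, 50), Q2 [50, 69.8), Q3 [69.8, 87.5), Q4 [87.5, 100]) plus
cardiovascular (CV) and non-CV death. Cycles are 28 days over a 28-year
horizon. Per cycle *t* with attained age *a(t)*:

* deaths first: CV and all-cause mortality come from parametric survival
  fits S(t) (exponential, Weibull, log-normal, log-logistic, Gompertz,
  generalised gamma; lowest AIC wins), with
  `p_cv(t) = 1 − S(t+Δ)/S(t)` and non-CV mortality
  `p_noncv = min(p_allcause − p_cv, cap)` where the cap is the cause-deleted
  general-population probability `qx(a) · (1 − cv_fraction(a))` at the
  attained age, sex-weighted and rescaled to the cycle;
* survivors then move among KCCQ quartiles by a row-stochastic matrix
  estimated from 30-day assessment panels;
* expected heart-failure events follow a marginal log-linear (GEE-type)
  model, `E[events per cycle] = exp(β₀ + β_age·a(t) + β_sex + β_race)`,
  evaluated at the cohort covariate mix — so event risk rises as the cohort
  ages;
* life years and QALYs accrue on the trapezoid of cycle-start/cycle-end
  occupancy (half-cycle correction), with per-state utilities, an
  age-related decrement (−0.0051 per year), one-off event/adverse-event
  disutilities, and 3.5% annual discounting;
* the active arm blends active and control risk sets by the fraction still
  on treatment under a (log-normal) discontinuation curve.

Because the source trial's patient-level data are confidential, the package
ships a synthetic trial generator with the same statistical structure, so
estimation, engine and validation are all exercised on data whose
generating truth is known. See the vignette
(`vignettes/hf-cohort-model.Rmd`) for the modelling assumptions, defaults
and their rationale.

## Worked example

```r
library(hfmarkov)

trial <- generate_trial(trial_config(n_per_arm = 4000, seed = 1))
model <- estimate_model(trial,
                        mortality_families = c("exponential", "weibull"),
                        discontinuation_families = c("exponential", "lognormal"))

soc <- trace_summary(run_cohort(model, "control"))
fin <- trace_summary(run_cohort(model, "active"))
cat(sprintf("SoC:        %.2f LY, %.2f discounted LY, %.2f discounted QALY\n",
            soc$ly, soc$ly_disc, soc$qaly_disc))
cat(sprintf("finerenone: %.2f LY, %.2f discounted LY, %.2f discounted QALY\n",
            fin$ly, fin$ly_disc, fin$qaly_disc))
#> SoC:        16.17 LY, 11.41 discounted LY, 8.11 discounted QALY
#> finerenone: 16.46 LY, 11.60 discounted LY, 8.24 discounted QALY

# external validation configuration: on-treatment window of 29 months,
# discontinuation zeroed, counts scaled to 3000 patients per arm
ev <- apply_external_validation_settings(model, age = 72)
model_event_counts(ev, arm_n = c(active = 3000, control = 3000))
#>     outcome     arm     count
#> 1 CV_deaths  active 138.56992
#> 2       HHF  active 510.14073
#> 3      UHFV  active  81.98346
#> 4 CV_deaths control 170.99121
#> 5       HHF control 760.15977
#> 6      UHFV control 132.90557
```

The LY/QALY totals are lifetime per-patient expectations for each arm; the
event counts are the model's projected trial-scale totals over the
29-month on-treatment window, the quantities one compares against observed
trial counts with `external_validation()`. With synthetic inputs the
magnitudes differ from any published analysis — what carries over are the
mechanisms (treatment effect direction, age sensitivity of event counts,
life-table-capped mortality), which is exactly what the validation suite
checks.

The published external-validation reference counts are bundled:

```r
external_validation(reference_event_counts("model", 72),
                    reference_event_counts("trial"))
```

reproduces every published absolute and relative difference cell (e.g. CV
deaths in the finerenone arm: 155 projected vs 161 observed, difference 6,
3.7%).

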