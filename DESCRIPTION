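Package: hfmarkov
Title: Cohort State-Transition Modelling and Validation for Heart Failure with LVEF >= 40%
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A Markov cohort model of chronic heart failure with left
    ventricular ejection fraction of 40% or more, with health states defined
    by Kansas City Cardiomyopathy Questionnaire (KCCQ) total summary score
    quartiles plus cardiovascular and non-cardiovascular death. Includes a
    synthetic patient-level trial generator, estimation of model inputs from
    patient-level data (parametric survival extrapolation with AIC/BIC
    selection, marginal Poisson models for recurrent hospitalisation events,
    KCCQ transition matrices, per-cycle adverse-event probabilities), a
    28-day-cycle engine with life-table-capped non-CV mortality, half-cycle
    correction and discounting, scenario adapters for cross- and external
    validation, validation reporting, and deterministic and probabilistic
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
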