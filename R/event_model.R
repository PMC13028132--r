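#' Log-linear recurrent-event rate model
#'
#' Represents the marginal model for recurrent heart-failure events
#' (hospitalisation for HF or urgent HF visit): the expected number of events
#' per model cycle follows a log link in baseline age (continuous, per year),
#' sex (female reference) and race (White reference; Asian, Black, Other
#' contrasts). This is the container both for "true" generating models in the
#' synthetic trial and for models estimated with [fit_event_gee()].
#'
#' `rate_ref` parameterises the intercept on an interpretable scale: the
#' per-cycle event rate at `ref_age` for a cohort with covariate mix
#' (`male_fraction`, `race_mix`).
#'
#' @param event_type "HHF" or "UHFV".
#' @param arm "active" or "control".
#' @param rate_ref expected events per cycle of length `cycle_days` at
#'   `ref_age`, averaged over the covariate mix.
#' @param ref_age years (default 72, the trial mean baseline age).
#' @param age_coef log-rate increase per year of age.
#' @param sex_coef log-rate contrast for males vs females.
#' @param race_coefs named log-rate contrasts `c(Asian=, Black=, Other=)`
#'   relative to White.
#' @param male_fraction,race_mix covariate mix defining the reference rate.
#' @param cycle_days cycle length on which `rate_ref` is expressed.
#' @return An object of class `hf_event_model`.
#' @export
event_model <- function(event_type = c("HHF", "UHFV"),
                        arm = c("active", "control"),
                        rate_ref,
                        ref_age = 72,
                        age_coef = 0,
                        sex_coef = 0,
                        race_coefs = c(Asian = 0, Black = 0, Other = 0),
                        male_fraction = 0.545,
                        race_mix = default_race_mix(),
                        cycle_days = 28) {
  event_type <- match.arg(event_type)
  arm <- match.arg(arm)
  stopifnot(rate_ref >= 0, cycle_days > 0)
  race_coefs <- race_coefs[c("Asian", "Black", "Other")]
  if (anyNA(race_coefs)) stop("race_coefs must name Asian, Black and Other")
  assert_mix(race_mix, "race_mix")
  if (rate_ref == 0) {
    coefs <- c(intercept = -Inf, age = 0, sexmale = 0,
               raceAsian = 0, raceBlack = 0, raceOther = 0)
  } else {
    # solve the intercept so the mix-averaged rate at ref_age equals rate_ref
    mix_factor <- mix_contrast_factor(sex_coef, race_coefs, male_fraction, race_mix)
    intercept <- log(rate_ref) - age_coef * ref_age - log(mix_factor)
    coefs <- c(intercept = intercept, age = age_coef, sexmale = sex_coef,
               raceAsian = unname(race_coefs["Asian"]),
               raceBlack = unname(race_coefs["Black"]),
               raceOther = unname(race_coefs["Other"]))
  }
  new_event_model(event_type, arm, coefs, cycle_days,
                  zero_rate = rate_ref == 0)
}

#' Default race composition
#'
#' Race mix of the emulated trial population (a large international HF
#' trial): predominantly White with a sizeable Asian minority.
#'
#' @return Named probability vector (White, Asian, Black, Other).
#' @export
default_race_mix <- function() {
  c(White = 0.78, Asian = 0.17, Black = 0.02, Other = 0.03)
}

new_event_model <- function(event_type, arm, coefficients, cycle_days,
                            vcov = NULL, zero_rate = FALSE, dropped = character()) {
  structure(
    list(event_type = event_type, arm = arm, coefficients = coefficients,
         cycle_days = cycle_days, vcov = vcov, zero_rate = zero_rate,
         dropped = dropped),
    class = "hf_event_model"
  )
}

# average of exp(contrasts) over the sex x race mix (sex and race independent)
mix_contrast_factor <- function(sex_coef, race_coefs, male_fraction, race_mix) {
  sex_part <- (1 - male_fraction) + male_fraction * exp(sex_coef)
  race_part <- race_mix["White"] +
    race_mix["Asian"] * exp(race_coefs["Asian"]) +
    race_mix["Black"] * exp(race_coefs["Black"]) +
    race_mix["Other"] * exp(race_coefs["Other"])
  unname(sex_part * race_part)
}

#' Per-cycle event rate for an individual
#'
#' @param model an `hf_event_model`.
#' @param age years.
#' @param sex "male"/"female".
#' @param race "White"/"Asian"/"Black"/"Other".
#' @param cycle_days length of the cycle the rate should refer to (rates are
#'   rescaled linearly from the model's own cycle basis).
#' @return Non-negative expected events per cycle.
#' @export
event_rate_individual <- function(model, age, sex, race,
                                  cycle_days = model$cycle_days) {
  if (model$zero_rate) return(rep(0, length(age)))
  b <- model$coefficients
  lp <- b["intercept"] + b["age"] * age +
    b["sexmale"] * (sex == "male") +
    b["raceAsian"] * (race == "Asian") +
    b["raceBlack"] * (race == "Black") +
    b["raceOther"] * (race == "Other")
  unname(exp(lp)) * cycle_days / model$cycle_days
}

#' Per-cycle event rate for a cohort covariate mix
#'
#' Averages the individual log-linear rate over the sex and race composition
#' of the cohort at a given attained age.
#'
#' @inheritParams event_rate_individual
#' @param male_fraction,race_mix cohort composition.
#' @return Non-negative expected events per cycle per alive cohort member.
#' @export
event_rate_cohort <- function(model, age, male_fraction, race_mix,
                              cycle_days = model$cycle_days) {
  if (model$zero_rate) return(rep(0, length(age)))
  b <- model$coefficients
  mf <- mix_contrast_factor(
    b["sexmale"],
    c(Asian = unname(b["raceAsian"]), Black = unname(b["raceBlack"]),
      Other = unname(b["raceOther"])),
    male_fraction, race_mix
  )
  unname(exp(b["intercept"] + b["age"] * age)) * mf *
    cycle_days / model$cycle_days
}

#' @export
print.hf_event_model <- function(x, ...) {
  cat("<hf_event_model>", x$event_type, "/", x$arm,
      if (x$zero_rate) "(zero-rate)" else "", "\n")
  cat("  per-", x$cycle_days, "-day-cycle log-linear coefficients:\n", sep = "")
  print(round(x$coefficients, 5))
  invisible(x)
}
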