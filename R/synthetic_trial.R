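#' Configuration for the synthetic trial generator
#'
#' Defines the generating process for a two-arm randomised HF trial with the
#' structure the cohort model assumes: truncated-normal baseline age, fixed
#' sex/race mixes, KCCQ baseline drawn by quartile occupancy, recurrent
#' HHF/UHFV events from per-cycle log-linear rates, cause-specific
#' (CV / non-CV) death times with first-event-wins competing risks,
#' log-normal treatment discontinuation in the active arm, and a monthly
#' KCCQ quartile transition process.
#'
#' Defaults emulate the pivotal FINEARTS-HF population: mean age 72 (SD 10,
#' truncated to 40-97), 54.5% male, baseline KCCQ quartile occupancy
#' 23.95/26.15/24.55/25.35%, and a follow-up of 29 months matching the
#' on-treatment external-validation window.
#'
#' @param n_per_arm patients per arm (>= 1).
#' @param seed integer RNG seed; generation is fully reproducible.
#' @param age_mean,age_sd,age_bounds truncated-normal baseline age (years).
#' @param male_fraction probability of male sex.
#' @param race_mix named probabilities (White, Asian, Black, Other), sum 1.
#' @param kccq_occupancy baseline KCCQ quartile probabilities (Q1..Q4), sum 1.
#' @param true_event_models nested list `[[event_type]][[arm]]` of
#'   [event_model()] objects giving the generating per-cycle rates.
#' @param true_mortality nested list `[[arm]][[cause]]` of parametric hazard
#'   specs, e.g. `list(family = "exponential", rate = 0.02)` with time in
#'   years; families: exponential, weibull, lognormal.
#' @param true_discontinuation parametric spec for time to discontinuation
#'   (active arm), default log-normal with median 28 months.
#' @param kccq_dynamics 4x4 row-stochastic matrix of 30-day quartile moves.
#' @param followup_days administrative censoring time.
#' @return Object of class `hf_trial_config`.
#' @export
trial_config <- function(n_per_arm,
                         seed = 1L,
                         age_mean = 72, age_sd = 10, age_bounds = c(40, 97),
                         male_fraction = 0.545,
                         race_mix = default_race_mix(),
                         kccq_occupancy = c(Q1 = 0.2395, Q2 = 0.2615,
                                            Q3 = 0.2455, Q4 = 0.2535),
                         true_event_models = default_true_event_models(),
                         true_mortality = default_true_mortality(),
                         true_discontinuation = list(family = "lognormal",
                                                     meanlog = log(28 / 12),
                                                     sdlog = 1.1),
                         kccq_dynamics = default_kccq_dynamics(),
                         followup_days = 29 * MONTH_DAYS) {
  if (!is.numeric(n_per_arm) || n_per_arm < 1) stop("n_per_arm must be >= 1")
  stopifnot_prob(male_fraction, "male_fraction")
  assert_mix(race_mix, "race_mix")
  assert_mix(kccq_occupancy, "kccq_occupancy")
  assert_row_stochastic(kccq_dynamics)
  stopifnot(age_sd > 0, age_bounds[1] < age_bounds[2], followup_days > 0)
  structure(
    list(n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
         male_fraction = male_fraction, race_mix = race_mix,
         kccq_occupancy = kccq_occupancy,
         true_event_models = true_event_models,
         true_mortality = true_mortality,
         true_discontinuation = true_discontinuation,
         kccq_dynamics = kccq_dynamics,
         followup_days = followup_days),
    class = "hf_trial_config"
  )
}

#' Default generating event-rate models
#'
#' Per-28-day-cycle HHF and UHFV rates at age 72 of roughly 0.0056/0.0081
#' (active/control) for HHF and 0.00076/0.00143 for UHFV, with log-linear age
#' coefficients of 0.02/yr (HHF) and 0.065/yr (UHFV) and a small male
#' contrast. Magnitudes are calibrated once to the published on-treatment
#' event counts of the pivotal trial.
#'
#' @return Nested list `[[event_type]][[arm]]` of `hf_event_model`s.
#' @export
default_true_event_models <- function() {
  list(
    HHF = list(
      active = event_model("HHF", "active", rate_ref = 0.0056,
                           age_coef = 0.02, sex_coef = 0.05),
      control = event_model("HHF", "control", rate_ref = 0.0081,
                            age_coef = 0.02, sex_coef = 0.05)
    ),
    UHFV = list(
      active = event_model("UHFV", "active", rate_ref = 0.00076,
                           age_coef = 0.065, sex_coef = 0.05),
      control = event_model("UHFV", "control", rate_ref = 0.00143,
                            age_coef = 0.065, sex_coef = 0.05)
    )
  )
}

#' Default generating mortality hazards
#'
#' Exponential cause-specific hazards per year: CV death 0.021 (active) /
#' 0.0245 (control), non-CV death 0.018 in both arms.
#'
#' @return Nested list `[[arm]][[cause]]`.
#' @export
default_true_mortality <- function() {
  list(
    active = list(CV = list(family = "exponential", rate = 0.021),
                  nonCV = list(family = "exponential", rate = 0.018)),
    control = list(CV = list(family = "exponential", rate = 0.0245),
                   nonCV = list(family = "exponential", rate = 0.018))
  )
}

#' Default monthly KCCQ quartile dynamics
#'
#' A sticky band matrix: most patients stay in their quartile over 30 days,
#' with modest flow to adjacent quartiles.
#'
#' @return 4x4 row-stochastic matrix.
#' @export
default_kccq_dynamics <- function() {
  m <- rbind(
    c(0.86, 0.10, 0.03, 0.01),
    c(0.10, 0.76, 0.11, 0.03),
    c(0.03, 0.11, 0.76, 0.10),
    c(0.01, 0.03, 0.10, 0.86)
  )
  dimnames(m) <- list(paste0("Q", 1:4), paste0("Q", 1:4))
  m / rowSums(m)
}

# draw n event times (in years) from a simple parametric hazard spec
draw_parametric_times <- function(spec, n) {
  switch(spec$family,
    exponential = if (spec$rate <= 0) rep(Inf, n) else stats::rexp(n, spec$rate),
    weibull = stats::rweibull(n, spec$shape, spec$scale),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    stop("unsupported hazard family: ", spec$family)
  )
}

# vectorised categorical draw given an n x k probability matrix (rows sum 1)
draw_categorical <- function(prob) {
  u <- stats::runif(nrow(prob))
  cum <- t(apply(prob, 1, cumsum))
  1L + rowSums(u > cum + 1e-15)
}

#' Generate a synthetic two-arm trial
#'
#' Simulates patient-level data under the generating process in `config`.
#' Recurrent events are drawn as a piecewise-constant-rate Poisson process
#' evaluated per 28-day cycle with the patient's attained age (baseline age
#' plus follow-up time); death is first-event-wins between the CV and non-CV
#' cause-specific times; events and KCCQ assessments stop at the earlier of
#' death and censoring.
#'
#' @param config an [trial_config()] object.
#' @return An object of class `hf_trial`: list with data.frames `patients`
#'   (one row per patient: covariates, `death_time`/`death_cause` if death
#'   occurred before censoring, `discontinuation_time`, `censor_time`, all
#'   times in days), `events` (long: `patient_id`, `time_days`,
#'   `event_type`), `kccq` (long: `patient_id`, `time_days`, `score` at
#'   30-day intervals), plus the `config`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "hf_trial_config"))
  with_seed(config$seed, {
    arms <- lapply(c(active = "active", control = "control"),
                   function(a) generate_arm(config, a))
    patients <- rbind(arms$active$patients, arms$control$patients)
    events <- rbind(arms$active$events, arms$control$events)
    kccq <- rbind(arms$active$kccq, arms$control$kccq)
    rownames(patients) <- NULL
    structure(list(patients = patients, events = events, kccq = kccq,
                   config = config),
              class = "hf_trial")
  })
}

generate_arm <- function(config, arm) {
  n <- config$n_per_arm
  id <- sprintf("%s%05d", if (arm == "active") "A" else "C", seq_len(n))

  # truncated-normal age by inverse-CDF so draws are a monotone map of runif
  lo <- stats::pnorm(config$age_bounds[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_bounds[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)

  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  race <- names(config$race_mix)[draw_categorical(
    matrix(config$race_mix, n, 4, byrow = TRUE))]

  bounds <- kccq_bounds()
  band0 <- draw_categorical(matrix(config$kccq_occupancy, n, 4, byrow = TRUE))
  kccq0 <- bounds[band0] +
    stats::runif(n) * (bounds[band0 + 1L] - bounds[band0])

  # competing-risk death: first of the cause-specific times wins
  t_cv <- draw_parametric_times(config$true_mortality[[arm]]$CV, n) * DAYS_PER_YEAR
  t_ncv <- draw_parametric_times(config$true_mortality[[arm]]$nonCV, n) * DAYS_PER_YEAR
  death_all <- pmin(t_cv, t_ncv)
  cause <- ifelse(t_cv <= t_ncv, "CV", "nonCV")
  censor <- rep(config$followup_days, n)
  death_obs <- ifelse(death_all <= censor, death_all, NA_real_)
  cause_obs <- ifelse(death_all <= censor, cause, NA_character_)

  disc <- rep(NA_real_, n)
  if (arm == "active") {
    d <- draw_parametric_times(config$true_discontinuation, n) * DAYS_PER_YEAR
    end <- pmin(ifelse(is.na(death_obs), censor, death_obs), censor)
    disc <- ifelse(d <= end, d, NA_real_)
  }

  patients <- data.frame(
    patient_id = id, arm = arm, age_baseline = age, sex = sex, race = race,
    kccq_baseline = kccq0, death_time = death_obs, death_cause = cause_obs,
    discontinuation_time = disc, censor_time = censor,
    stringsAsFactors = FALSE
  )

  end_risk <- pmin(ifelse(is.na(death_obs), Inf, death_obs), censor)
  events <- simulate_recurrent_events(config, arm, patients, end_risk)
  kccq <- simulate_kccq_panel(config, patients, band0, end_risk)
  list(patients = patients, events = events, kccq = kccq)
}

simulate_recurrent_events <- function(config, arm, patients, end_risk) {
  n <- nrow(patients)
  cyc <- 28
  n_cycles <- ceiling(config$followup_days / cyc)
  out_id <- character(0); out_t <- numeric(0); out_type <- character(0)
  for (type in names(config$true_event_models)) {
    model <- config$true_event_models[[type]][[arm]]
    if (model$zero_rate) next
    for (c in seq_len(n_cycles)) {
      t0 <- (c - 1) * cyc
      at_risk <- end_risk > t0
      if (!any(at_risk)) break
      frac <- pmin(end_risk - t0, cyc) / cyc
      frac[!at_risk] <- 0
      age_now <- patients$age_baseline + t0 / DAYS_PER_YEAR
      mu <- event_rate_individual(model, age_now, patients$sex, patients$race) * frac
      k <- stats::rpois(n, mu)
      pos <- which(k > 0)
      if (length(pos)) {
        reps <- k[pos]
        t_ev <- t0 + stats::runif(sum(reps)) *
          rep(pmin(end_risk[pos] - t0, cyc), reps)
        out_id <- c(out_id, rep(patients$patient_id[pos], reps))
        out_t <- c(out_t, t_ev)
        out_type <- c(out_type, rep(type, sum(reps)))
      }
    }
  }
  data.frame(patient_id = out_id, time_days = out_t, event_type = out_type,
             stringsAsFactors = FALSE)
}

simulate_kccq_panel <- function(config, patients, band0, end_risk) {
  step <- 30
  bounds <- kccq_bounds()
  times <- seq(0, config$followup_days, by = step)
  n <- nrow(patients)
  band <- band0
  ids <- list(); tt <- list(); sc <- list()
  score <- patients$kccq_baseline
  for (j in seq_along(times)) {
    alive <- end_risk > times[j]
    if (j == 1L) alive <- rep(TRUE, n)  # baseline assessment always exists
    if (!any(alive)) break
    ids[[j]] <- patients$patient_id[alive]
    tt[[j]] <- rep(times[j], sum(alive))
    sc[[j]] <- score[alive]
    # evolve bands by the 30-day matrix for the next assessment
    band <- draw_categorical(config$kccq_dynamics[band, , drop = FALSE])
    score <- bounds[band] + stats::runif(n) * (bounds[band + 1L] - bounds[band])
  }
  data.frame(patient_id = unlist(ids), time_days = unlist(tt),
             score = unlist(sc), stringsAsFactors = FALSE)
}

#' Baseline summary of a trial
#'
#' @param trial an `hf_trial` or a `patients` data.frame.
#' @return List with `n`, `mean_age`, `male_share`, `race_shares`,
#'   `kccq_occupancy` (Q1..Q4 shares using the model's quartile bounds).
#' @export
summarize_baseline <- function(trial) {
  pts <- if (inherits(trial, "hf_trial")) trial$patients else trial
  if (is.null(pts) || !nrow(pts)) stop("empty patient collection")
  band <- kccq_band(pts$kccq_baseline)
  occ <- as.numeric(table(factor(band, levels = 1:4))) / nrow(pts)
  list(
    n = nrow(pts),
    mean_age = mean(pts$age_baseline),
    male_share = mean(pts$sex == "male"),
    race_shares = prop.table(table(factor(
      pts$race, levels = c("White", "Asian", "Black", "Other")))),
    kccq_occupancy = stats::setNames(occ, paste0("Q", 1:4))
  )
}

#' Write / read a trial as CSV files
#'
#' `write_trial()` writes `patients.csv` (wide baselines and outcome times),
#' `events.csv` and `kccq.csv` (long) into `dir`; `read_trial()` reads them
#' back (without the generating config).
#'
#' @param trial an `hf_trial`.
#' @param dir directory (created if missing).
#' @return `write_trial()` the directory invisibly; `read_trial()` an
#'   `hf_trial` (config `NULL`).
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "hf_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(trial$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(trial$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(trial$kccq, file.path(dir, "kccq.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  structure(
    list(patients = utils::read.csv(file.path(dir, "patients.csv"),
                                    stringsAsFactors = FALSE),
         events = utils::read.csv(file.path(dir, "events.csv"),
                                  stringsAsFactors = FALSE),
         kccq = utils::read.csv(file.path(dir, "kccq.csv"),
                                stringsAsFactors = FALSE),
         config = NULL),
    class = "hf_trial"
  )
}

#' @export
print.hf_trial <- function(x, ...) {
  cat("<hf_trial>", nrow(x$patients), "patients,",
      nrow(x$events), "events,", nrow(x$kccq), "KCCQ assessments\n")
  invisible(x)
}
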