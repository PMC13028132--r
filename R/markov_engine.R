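STATES <- c("Q1", "Q2", "Q3", "Q4", "CV_death", "nonCV_death")

#' Model specification
#'
#' Settings of the cohort state-transition model: four alive states defined
#' by KCCQ total-summary-score quartiles plus CV-death and non-CV-death
#' absorbing states, a 28-day cycle over a 28-year horizon, 3.5% annual
#' discounting, per-state utilities with an age-related decrement, one-off
#' disutilities per expected HF event, and a per-cycle adverse-event basket.
#'
#' @param cycle_days cycle length in days (28 in the base case; the
#'   Cohen-settings adapter switches to calendar months).
#' @param horizon_years model horizon.
#' @param start_age cohort mean age at baseline (years).
#' @param male_fraction fixed male share used for life-table lookups and
#'   event-rate covariate mixing.
#' @param race_mix race composition for event-rate mixing.
#' @param start_occupancy baseline occupancy of Q1..Q4 (sums to 1).
#' @param discount_annual annual discount rate.
#' @param discount_dialect `"from_zero"` discounts from time zero;
#'   `"exempt_first_year"` leaves the first year undiscounted and shifts the
#'   discounting clock by one year thereafter.
#' @param utilities per-state utilities (Q1..Q4), each in \[-1, 1\].
#' @param age_decrement utility change per year of attained age beyond
#'   baseline (default -0.0051).
#' @param event_disutilities one-off QALY decrements per expected event,
#'   named `HHF` and `UHFV`.
#' @param ae adverse-event basket: data.frame with columns `name`, `prob`
#'   (per cycle of length `cycle_days_src`), `cycle_days_src`, `disutility`;
#'   may have zero rows.
#' @param ae_disutilities_on apply AE disutilities?
#' @param hf_disutility_first_year apply HF-event disutilities during the
#'   first model year? (The Cohen comparison setting turns this off.)
#' @param scenario free-text scenario label.
#' @return Object of class `hf_model_spec`.
#' @export
model_spec <- function(cycle_days = 28,
                       horizon_years = 28,
                       start_age = 72,
                       male_fraction = 0.545,
                       race_mix = default_race_mix(),
                       start_occupancy = c(Q1 = 0.2395, Q2 = 0.2615,
                                           Q3 = 0.2455, Q4 = 0.2535),
                       discount_annual = 0.035,
                       discount_dialect = c("from_zero", "exempt_first_year"),
                       utilities = c(Q1 = 0.64, Q2 = 0.74, Q3 = 0.81, Q4 = 0.86),
                       age_decrement = -0.0051,
                       event_disutilities = c(HHF = 0.035, UHFV = 0.015),
                       ae = default_ae_basket(),
                       ae_disutilities_on = TRUE,
                       hf_disutility_first_year = TRUE,
                       scenario = "base_case") {
  discount_dialect <- match.arg(discount_dialect)
  assert_mix(start_occupancy, "start_occupancy")
  if (any(abs(utilities) > 1)) stop("utilities must lie in [-1, 1]")
  stopifnot(cycle_days > 0, horizon_years * DAYS_PER_YEAR >= cycle_days,
            start_age > 0, discount_annual >= 0)
  stopifnot_prob(male_fraction, "male_fraction")
  structure(
    list(states = STATES, cycle_days = cycle_days,
         horizon_years = horizon_years, start_age = start_age,
         male_fraction = male_fraction, race_mix = race_mix,
         start_occupancy = start_occupancy,
         discount_annual = discount_annual,
         discount_dialect = discount_dialect,
         utilities = utilities, age_decrement = age_decrement,
         event_disutilities = event_disutilities,
         ae = ae, ae_disutilities_on = ae_disutilities_on,
         hf_disutility_first_year = hf_disutility_first_year,
         scenario = scenario),
    class = "hf_model_spec"
  )
}

#' Default adverse-event basket
#'
#' Per-cycle probabilities for the most material adverse events (an
#' incidence of at least 1% in either trial arm), derived from plausible
#' trial shares over a 32-month median follow-up via
#' [proportion_to_cycle_probability()], with small one-off disutilities.
#'
#' @return data.frame with columns `name`, `prob`, `cycle_days_src`,
#'   `disutility`.
#' @export
default_ae_basket <- function() {
  shares <- c(hyperkalaemia = 0.07, pneumonia = 0.04,
              atrial_fibrillation = 0.04, acute_kidney_injury = 0.03)
  fup <- 32 * MONTH_DAYS
  data.frame(
    name = names(shares),
    prob = vapply(shares, function(s)
      proportion_to_cycle_probability(s, fup, 28)$value, numeric(1)),
    cycle_days_src = 28,
    disutility = c(0.010, 0.020, 0.010, 0.010),
    stringsAsFactors = FALSE
  )
}

#' Per-arm model inputs
#'
#' @param transition 4x4 row-stochastic KCCQ transition matrix on the 30-day
#'   assessment grid, mapped one-to-one onto the model cycle.
#' @param cv,allcause CV-death and all-cause-death inputs: either an
#'   `hf_survival_fit` (time in years) or an [cycle_prob()] constant.
#' @param events list with `HHF` and `UHFV` [event_model()]s.
#' @return Object of class `hf_arm_inputs`.
#' @export
arm_inputs <- function(transition, cv, allcause, events) {
  assert_row_stochastic(transition)
  stopifnot(all(c("HHF", "UHFV") %in% names(events)))
  structure(list(transition = transition, cv = cv, allcause = allcause,
                 events = events),
            class = "hf_arm_inputs")
}

#' Assembled cohort model
#'
#' @param spec an [model_spec()].
#' @param active,control [arm_inputs()] for each arm.
#' @param life_table an `hf_life_table` used to cap non-CV mortality, or
#'   `NULL` for no cap.
#' @param discontinuation active-arm treatment discontinuation: an
#'   `hf_survival_fit` (years), a [cycle_prob()], or `NULL` for none. After
#'   discontinuation the cohort carries control-arm risks.
#' @return Object of class `hf_model`.
#' @export
hf_model <- function(spec, active, control, life_table = NULL,
                     discontinuation = NULL) {
  stopifnot(inherits(spec, "hf_model_spec"),
            inherits(active, "hf_arm_inputs"),
            inherits(control, "hf_arm_inputs"))
  if (!is.null(life_table)) stopifnot(inherits(life_table, "hf_life_table"))
  structure(list(spec = spec,
                 arms = list(active = active, control = control),
                 life_table = life_table,
                 discontinuation = discontinuation),
            class = "hf_model")
}

#' Per-cycle mortality schedule
#'
#' Builds the per-cycle CV and non-CV death probabilities over the horizon.
#' The model-implied non-CV probability is the all-cause minus the CV
#' probability (floored at zero) and is capped each cycle at the
#' sex-weighted, cause-deleted life-table probability at the attained
#' (floored integer) age, converted to the cycle length.
#'
#' @param cv,allcause `hf_survival_fit` or `hf_cycle_prob` inputs.
#' @param life_table `hf_life_table` or `NULL` (no cap).
#' @param spec an [model_spec()].
#' @return data.frame with columns `cycle`, `age`, `p_cv`, `p_noncv`.
#' @export
build_mortality_schedule <- function(cv, allcause, life_table, spec) {
  dy <- spec$cycle_days / DAYS_PER_YEAR
  n_cycles <- ceiling(spec$horizon_years / dy)
  t0 <- (seq_len(n_cycles) - 1) * dy
  t1 <- seq_len(n_cycles) * dy
  p_cv <- vapply(seq_len(n_cycles),
                 function(i) cond_event_prob(cv, t0[i], t1[i]), numeric(1))
  p_ac <- vapply(seq_len(n_cycles),
                 function(i) cond_event_prob(allcause, t0[i], t1[i]), numeric(1))
  p_ncv <- pmax(p_ac - p_cv, 0)
  age <- floor(spec$start_age + t0)
  if (!is.null(life_table)) {
    ann <- life_table_noncv_annual(life_table, age, spec$male_fraction)
    cap <- 1 - (1 - ann)^dy  # per-cycle scale, dy in years
    p_ncv <- pmin(p_ncv, cap)
  }
  if (any(p_cv + p_ncv > 1 + 1e-12)) {
    stop("p_cv + p_noncv exceeds 1 in at least one cycle")
  }
  data.frame(cycle = seq_len(n_cycles), age = age, p_cv = p_cv, p_noncv = p_ncv)
}

#' Advance the cohort one cycle
#'
#' Deaths are applied first, competing-risk style, to every alive state;
#' survivors are then redistributed among the KCCQ states by the transition
#' matrix. The death states are absorbing.
#'
#' @param occupancy length-6 occupancy vector (Q1..Q4, CV_death,
#'   nonCV_death) summing to 1.
#' @param transition 4x4 row-stochastic matrix.
#' @param p_cv,p_noncv per-cycle death probabilities.
#' @return New length-6 occupancy vector.
#' @export
step_cohort <- function(occupancy, transition, p_cv, p_noncv) {
  if (any(occupancy < -1e-12)) stop("negative occupancy")
  assert_row_stochastic(transition)
  stopifnot_prob(c(p_cv, p_noncv))
  if (p_cv + p_noncv > 1) stop("p_cv + p_noncv exceeds 1")
  step_cohort_fast(occupancy, transition, p_cv, p_noncv)
}

step_cohort_fast <- function(occupancy, transition, p_cv, p_noncv) {
  alive <- occupancy[1:4]
  a <- sum(alive)
  survivors <- alive * (1 - p_cv - p_noncv)
  c(as.vector(survivors %*% transition),
    occupancy[5] + a * p_cv,
    occupancy[6] + a * p_noncv)
}

#' Expected events in a cycle
#'
#' Expected HHF or UHFV count per cohort member-cycle: alive mass times the
#' per-cycle log-linear rate evaluated at the current cohort mean age and
#' the cohort sex/race mix.
#'
#' @param occupancy length-6 occupancy vector (or its alive mass as a
#'   scalar).
#' @param model an `hf_event_model`.
#' @param cohort_age attained cohort mean age (years).
#' @param male_fraction,race_mix cohort composition.
#' @param cycle_days engine cycle length.
#' @return Expected events in the cycle.
#' @export
expected_events <- function(occupancy, model, cohort_age,
                            male_fraction = 0.545,
                            race_mix = default_race_mix(),
                            cycle_days = model$cycle_days) {
  alive <- if (length(occupancy) == 1L) occupancy else sum(occupancy[1:4])
  rate <- event_rate_cohort(model, cohort_age, male_fraction, race_mix,
                            cycle_days)
  if (any(rate < 0)) stop("internal error: negative event rate")
  alive * rate
}

on_treatment_fraction <- function(x, t0_years, cycle_days) {
  if (is.null(x)) return(rep(1, length(t0_years)))
  if (inherits(x, "hf_survival_fit")) return(survival_prob(x, t0_years))
  if (inherits(x, "hf_cycle_prob")) {
    return((1 - x$value)^(t0_years * DAYS_PER_YEAR / x$cycle_days))
  }
  stop("discontinuation must be NULL, an hf_survival_fit or an hf_cycle_prob")
}

discount_factors <- function(t0_years, rate, dialect) {
  if (rate == 0) return(rep(1, length(t0_years)))
  switch(dialect,
    from_zero = (1 + rate)^(-t0_years),
    exempt_first_year = ifelse(t0_years < 1, 1, (1 + rate)^(-(t0_years - 1)))
  )
}

ae_cycle_probs <- function(ae, cycle_days) {
  if (is.null(ae) || !nrow(ae)) return(numeric(0))
  1 - (1 - ae$prob)^(cycle_days / ae$cycle_days_src)
}

#' Run the cohort model for one arm
#'
#' Produces the full cycle-by-cycle trace: state occupancy, expected HHF /
#' UHFV / adverse-event counts, life years and QALYs (undiscounted and
#' discounted), all half-cycle corrected via the trapezoid of cycle-start
#' and cycle-end occupancy. For the active arm the per-cycle risk set is a
#' blend of active and control inputs weighted by the fraction of the cohort
#' still on treatment under the discontinuation curve (patients who stop
#' treatment carry control-arm risks thereafter).
#'
#' @param model an [hf_model()].
#' @param arm "control" or "active".
#' @return data.frame of class `hf_cohort_trace` with one row per cycle and
#'   attributes `spec`, `arm`, `start_occupancy`.
#' @export
run_cohort <- function(model, arm = c("control", "active")) {
  arm <- match.arg(arm)
  spec <- model$spec
  dy <- spec$cycle_days / DAYS_PER_YEAR
  n_cycles <- ceiling(spec$horizon_years / dy)
  if (n_cycles < 1L) stop("horizon shorter than one cycle")
  t0 <- (seq_len(n_cycles) - 1) * dy
  t1 <- seq_len(n_cycles) * dy
  age_t <- spec$start_age + t0

  sched_a <- build_mortality_schedule(model$arms$active$cv,
                                      model$arms$active$allcause,
                                      model$life_table, spec)
  sched_c <- build_mortality_schedule(model$arms$control$cv,
                                      model$arms$control$allcause,
                                      model$life_table, spec)
  w <- if (arm == "active") {
    on_treatment_fraction(model$discontinuation, t0, spec$cycle_days)
  } else rep(0, n_cycles)
  if (arm == "control") {
    p_cv <- sched_c$p_cv; p_ncv <- sched_c$p_noncv
  } else {
    p_cv <- w * sched_a$p_cv + (1 - w) * sched_c$p_cv
    p_ncv <- w * sched_a$p_noncv + (1 - w) * sched_c$p_noncv
  }
  mf <- spec$male_fraction; rmix <- spec$race_mix
  rate_mix <- function(type) {
    ra <- event_rate_cohort(model$arms$active$events[[type]], age_t, mf, rmix,
                            spec$cycle_days)
    rc <- event_rate_cohort(model$arms$control$events[[type]], age_t, mf, rmix,
                            spec$cycle_days)
    if (arm == "control") rc else w * ra + (1 - w) * rc
  }
  r_hhf <- rate_mix("HHF")
  r_uhfv <- rate_mix("UHFV")
  p_ae <- ae_cycle_probs(spec$ae, spec$cycle_days)

  P_a <- model$arms$active$transition
  P_c <- model$arms$control$transition
  assert_row_stochastic(P_a); assert_row_stochastic(P_c)

  occ <- matrix(NA_real_, n_cycles + 1L, 6L,
                dimnames = list(NULL, STATES))
  occ[1L, ] <- c(spec$start_occupancy, 0, 0)
  alive_start <- numeric(n_cycles); alive_end <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    P <- if (arm == "control" || w[t] == 1) {
      if (arm == "control") P_c else P_a
    } else w[t] * P_a + (1 - w[t]) * P_c
    occ[t + 1L, ] <- step_cohort_fast(occ[t, ], P, p_cv[t], p_ncv[t])
    alive_start[t] <- sum(occ[t, 1:4])
    alive_end[t] <- sum(occ[t + 1L, 1:4])
    leak <- abs(sum(occ[t + 1L, ]) - 1)
    if (leak > 1e-9) stop("occupancy leak of ", leak, " at cycle ", t)
  }
  alive_trap <- (alive_start + alive_end) / 2

  events_hhf <- alive_trap * r_hhf
  events_uhfv <- alive_trap * r_uhfv
  events_ae <- alive_trap * sum(p_ae)

  v <- discount_factors(t0, spec$discount_annual, spec$discount_dialect)
  ly <- alive_trap * dy
  trace <- data.frame(
    cycle = seq_len(n_cycles), t0_years = t0, t1_years = t1, age = age_t,
    occ[-1L, , drop = FALSE],
    alive = alive_end, w_on_treatment = if (arm == "active") w else rep(NA_real_, n_cycles),
    p_cv = p_cv, p_noncv = p_ncv,
    events_hhf = events_hhf, events_uhfv = events_uhfv, events_ae = events_ae,
    ly = ly, ly_disc = ly * v
  )
  attr(trace, "spec") <- spec
  attr(trace, "arm") <- arm
  attr(trace, "start_occupancy") <- occ[1L, ]
  attr(trace, "occ_start") <- occ[-(n_cycles + 1L), , drop = FALSE]
  trace <- accrue_qaly(trace)
  trace$cum_hhf <- cumsum(trace$events_hhf)
  trace$cum_uhfv <- cumsum(trace$events_uhfv)
  trace$cum_ae <- cumsum(trace$events_ae)
  trace$cum_ly <- cumsum(trace$ly)
  trace$cum_ly_disc <- cumsum(trace$ly_disc)
  trace$cum_qaly <- cumsum(trace$qaly)
  trace$cum_qaly_disc <- cumsum(trace$qaly_disc)
  class(trace) <- c("hf_cohort_trace", "data.frame")
  trace
}

#' Accrue quality-adjusted life years over a trace
#'
#' Per cycle, the QALY contribution is the trapezoid occupancy of each alive
#' state times its utility adjusted by the age-related decrement (utility +
#' decrement x years elapsed since baseline, evaluated at cycle start),
#' times the cycle length in years; minus one-off disutilities for the
#' expected HF events and adverse events of the cycle. Discounted variants
#' use the same factors as life years.
#'
#' @param trace an `hf_cohort_trace` (occupancy and event columns present).
#' @param utilities,age_decrement,event_disutilities overrides; default to
#'   the spec the trace was run with.
#' @return The trace with `qaly` and `qaly_disc` columns (re)computed.
#' @export
accrue_qaly <- function(trace, utilities = NULL, age_decrement = NULL,
                        event_disutilities = NULL) {
  spec <- attr(trace, "spec")
  if (is.null(utilities)) utilities <- spec$utilities
  if (is.null(age_decrement)) age_decrement <- spec$age_decrement
  if (is.null(event_disutilities)) event_disutilities <- spec$event_disutilities
  if (any(abs(utilities) > 1)) stop("utilities must lie in [-1, 1]")
  occ_start <- attr(trace, "occ_start")
  occ_end <- as.matrix(trace[, STATES])
  occ_trap <- (occ_start[, 1:4, drop = FALSE] + occ_end[, 1:4, drop = FALSE]) / 2
  dy <- spec$cycle_days / DAYS_PER_YEAR
  elapsed <- trace$t0_years
  u_adj <- outer(elapsed * age_decrement, rep(1, 4)) +
    matrix(utilities, nrow(trace), 4, byrow = TRUE)
  q_state <- rowSums(occ_trap * u_adj) * dy
  hf_on <- if (spec$hf_disutility_first_year) rep(1, nrow(trace)) else
    as.numeric(elapsed >= 1)
  disut <- hf_on * (trace$events_hhf * event_disutilities[["HHF"]] +
                    trace$events_uhfv * event_disutilities[["UHFV"]])
  if (isTRUE(spec$ae_disutilities_on) && !is.null(spec$ae) && nrow(spec$ae)) {
    p_ae <- ae_cycle_probs(spec$ae, spec$cycle_days)
    alive_trap <- (rowSums(occ_start[, 1:4, drop = FALSE]) +
                   rowSums(occ_end[, 1:4, drop = FALSE])) / 2
    disut <- disut + alive_trap * sum(p_ae * spec$ae$disutility)
  }
  v <- discount_factors(elapsed, spec$discount_annual, spec$discount_dialect)
  trace$qaly <- q_state - disut
  trace$qaly_disc <- trace$qaly * v
  trace
}

#' Summary outcomes of a trace
#'
#' @param trace an `hf_cohort_trace`.
#' @return List with total `ly`, `ly_disc`, `qaly`, `qaly_disc`, cumulative
#'   event counts and end-of-horizon death-state occupancies.
#' @export
trace_summary <- function(trace) {
  n <- nrow(trace)
  list(
    scenario = attr(trace, "spec")$scenario,
    arm = attr(trace, "arm"),
    ly = sum(trace$ly), ly_disc = sum(trace$ly_disc),
    qaly = sum(trace$qaly), qaly_disc = sum(trace$qaly_disc),
    hhf = sum(trace$events_hhf), uhfv = sum(trace$events_uhfv),
    ae = sum(trace$events_ae),
    cv_deaths = trace$CV_death[n], noncv_deaths = trace$nonCV_death[n]
  )
}

#' Cumulative outcomes at an intermediate time
#'
#' Linearly interpolates the cumulative event and death curves of a trace at
#' a time expressed in months (e.g. the 29-month on-treatment validation
#' window, which falls between cycle boundaries of the 28-day grid).
#'
#' @param trace an `hf_cohort_trace` run over at least `months`.
#' @param months target time in calendar months (365.25/12 days each).
#' @return List with `cv_deaths`, `noncv_deaths`, `hhf`, `uhfv` per cohort
#'   member at the target time.
#' @export
events_at <- function(trace, months) {
  spec <- attr(trace, "spec")
  t_target <- months / 12
  if (t_target > max(trace$t1_years) + 1e-12) {
    stop("trace horizon shorter than ", months, " months")
  }
  interp <- function(y) {
    stats::approx(c(0, trace$t1_years), c(0, y), xout = t_target,
                  rule = 2)$y
  }
  list(
    cv_deaths = interp(trace$CV_death),
    noncv_deaths = interp(trace$nonCV_death),
    hhf = interp(trace$cum_hhf),
    uhfv = interp(trace$cum_uhfv)
  )
}

#' Export a trace to CSV
#'
#' @param trace an `hf_cohort_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
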