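fake_fit <- function(aic, k = 2, bic = aic, endpoint = "discontinuation",
                     family = "weibull") {
  structure(list(family = family, aic = aic, bic = bic, k = k,
                 endpoint = endpoint),
            class = "hf_survival_fit")
}

test_that("exponential MLE recovers the generating hazard and its closed form", {
  set.seed(101)
  n <- 3000
  t_true <- rexp(n, 0.5)
  cens <- 3
  time <- pmin(t_true, cens)
  status <- as.integer(t_true <= cens)
  fit <- fit_parametric_survival(time, status, "exponential", "CV_death")
  lam <- fit$parameters[["rate"]]
  se <- lam / sqrt(sum(status))
  expect_lt(abs(lam - 0.5), 3 * se)
  # closed form: events / exposure
  expect_equal(lam, sum(status) / sum(time), tolerance = 1e-8)
  # AIC/BIC identities
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$k)
  expect_equal(fit$bic, -2 * fit$log_likelihood + fit$k * log(fit$n))
  # survival function monotone non-increasing from 1
  s <- survival_prob(fit, seq(0, 28, by = 0.5))
  expect_equal(s[1], 1)
  expect_true(all(diff(s) <= 0))
})

test_that("single-subject exponential fit gives the closed-form MLE 1/t", {
  fit <- fit_parametric_survival(4, 1, "exponential")
  expect_equal(fit$parameters[["rate"]], 1 / 4, tolerance = 1e-6)
})

test_that("degenerate survival inputs are rejected", {
  expect_error(fit_parametric_survival(c(1, 2), c(0, 0), "exponential"),
               "censored")
  expect_error(fit_parametric_survival(c(-1, 2), c(1, 1), "exponential"),
               "positive")
})

test_that("information-criterion selection recovers a log-normal generating family", {
  set.seed(2024)
  n <- 6000
  t_true <- rlnorm(n, meanlog = log(28 / 12), sdlog = 1.1)
  cens <- 29 / 12
  time <- pmin(t_true, cens)
  status <- as.integer(t_true <= cens)
  fits <- fit_survival_families(time, status, endpoint = "discontinuation")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  expect_equal(fits[[which.min(aics)]]$family, "lognormal")
  best <- select_best_fit(fits, "AIC")
  expect_equal(best$family, "lognormal")
  # identities hold for every family fitted
  for (f in fits) {
    expect_equal(f$aic, -2 * f$log_likelihood + 2 * f$k)
    expect_equal(f$bic, -2 * f$log_likelihood + f$k * log(f$n))
  }
})

test_that("best-fit selection: argmin, parsimony tie-break, BIC criterion", {
  fits <- list(fake_fit(100, k = 2), fake_fit(98, k = 2), fake_fit(103, k = 2))
  expect_equal(select_best_fit(fits, "AIC")$aic, 98)
  # within 2 AIC units the fewer-parameter family wins
  fits2 <- list(fake_fit(98.5, k = 1, family = "exponential"),
                fake_fit(98, k = 3, family = "generalised_gamma"))
  expect_equal(select_best_fit(fits2, "AIC")$family, "exponential")
  # BIC argmin can differ from the AIC winner
  fits3 <- list(fake_fit(98, k = 3, bic = 120),
                fake_fit(103, k = 2, bic = 110))
  expect_equal(select_best_fit(fits3, "BIC")$bic, 110)
  expect_error(select_best_fit(list(), "AIC"), "no fits")
  expect_error(
    select_best_fit(list(fake_fit(1), fake_fit(2, endpoint = "CV_death"))),
    "mix"
  )
})

test_that("rate-to-probability conversion uses the constant-hazard transform", {
  p <- rate_to_cycle_probability(3.56, 365.25 / 12)
  expect_equal(round(p$value, 4), 0.0030)
  expect_equal(rate_to_cycle_probability(0, 28)$value, 0)
  # annual hazard 12 over one month: 1 - exp(-1)
  p12 <- rate_to_cycle_probability(1200, 365.25 / 12)
  expect_equal(p12$value, 1 - exp(-1), tolerance = 1e-12)
  expect_error(rate_to_cycle_probability(-1), "non-negative")
})

test_that("proportion-to-probability conversion and its inverse", {
  expect_equal(proportion_to_cycle_probability(0, 900, 28)$value, 0)
  fup <- 32 * 365.25 / 12
  p <- proportion_to_cycle_probability(0.10, fup, 28)
  expect_equal(p$value, 1 - 0.9^(28 / fup), tolerance = 1e-12)
  expect_equal(round(p$value, 5), 0.00302)
  # applying p over followup/cycle cycles recovers the proportion
  expect_equal(1 - (1 - p$value)^(fup / 28), 0.10, tolerance = 1e-12)
  expect_error(proportion_to_cycle_probability(1, 900, 28), "\\[0, 1\\)")
  expect_error(proportion_to_cycle_probability(0.1, 10, 28), "cycle")
})

test_that("transition matrix estimation counts 30-day quartile moves", {
  # panels that never change band -> identity
  k1 <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                   time_days = rep(c(0, 30, 60), 2),
                   score = rep(c(20, 95), each = 3))
  m1 <- suppressWarnings(estimate_transition_matrix(k1))
  expect_equal(unname(m1), diag(4))
  # a start band with no observed moves warns explicitly
  k1b <- data.frame(patient_id = rep("a", 4), time_days = c(0, 30, 60, 90),
                    score = c(20, 55, 75, 75))
  expect_warning(estimate_transition_matrix(k1b), "Q4")

  # two observed moves out of Q1: one stay, one to Q2
  k2 <- data.frame(patient_id = c("a", "a", "b", "b"),
                   time_days = c(0, 30, 0, 30),
                   score = c(10, 20, 10, 55))
  m2 <- suppressWarnings(estimate_transition_matrix(k2))
  expect_equal(unname(m2[1, ]), c(0.5, 0.5, 0, 0))

  # boundary scores belong to the upper band (lower-closed bounds)
  expect_equal(kccq_band(c(50, 69.8, 87.5, 100)), c(2L, 3L, 4L, 4L))
  expect_equal(kccq_band(c(1, 49.999)), c(1L, 1L))

  # generated panels give a row-stochastic matrix to 1e-12
  tr <- generate_trial(trial_config(n_per_arm = 400, seed = 9))
  m <- estimate_transition_matrix(tr$kccq)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  expect_true(all(m >= 0))
})

test_that("marginal event model recovers generating coefficients within 3 SE", {
  cfg <- trial_config(n_per_arm = 10000, seed = 31)
  tr <- generate_trial(cfg)
  fit <- fit_event_gee(tr, "HHF", "control")
  se_age <- sqrt(fit$vcov["age", "age"])
  expect_lt(abs(fit$coefficients[["age"]] - 0.02), 3 * se_age)

  # covariate-free generation: all contrasts within 3 SE of zero
  ev_flat <- list(
    HHF = list(active = event_model("HHF", "active", 0.008),
               control = event_model("HHF", "control", 0.008)),
    UHFV = list(active = event_model("UHFV", "active", 0.002),
                control = event_model("UHFV", "control", 0.002))
  )
  tr0 <- generate_trial(trial_config(n_per_arm = 10000, seed = 32,
                                     true_event_models = ev_flat))
  fit0 <- fit_event_gee(tr0, "HHF", "control")
  for (nm in c("age", "sexmale", "raceAsian", "raceBlack", "raceOther")) {
    expect_lt(abs(fit0$coefficients[[nm]]), 3 * sqrt(fit0$vcov[nm, nm]))
  }
})

test_that("event model handles degenerate data and satisfies the score identity", {
  ev0 <- list(
    HHF = list(active = event_model("HHF", "active", 0),
               control = event_model("HHF", "control", 0)),
    UHFV = list(active = event_model("UHFV", "active", 0.002),
                control = event_model("UHFV", "control", 0.002))
  )
  tr <- generate_trial(trial_config(n_per_arm = 300, seed = 33,
                                    true_event_models = ev0))
  fit0 <- fit_event_gee(tr, "HHF", "control")
  expect_true(fit0$zero_rate)
  expect_equal(event_rate_cohort(fit0, 72, 0.545, default_race_mix()), 0)

  # Poisson score identity: fitted total equals observed total
  tr2 <- generate_trial(trial_config(n_per_arm = 2000, seed = 34))
  fit <- fit_event_gee(tr2, "HHF", "control")
  p <- tr2$patients[tr2$patients$arm == "control", ]
  end <- pmin(ifelse(is.na(p$death_time), Inf, p$death_time), p$censor_time)
  mu <- event_rate_individual(fit, p$age_baseline, p$sex, p$race) * end / 28
  observed <- sum(tr2$events$event_type == "HHF" &
                    tr2$events$patient_id %in% p$patient_id)
  expect_equal(sum(mu), observed, tolerance = 1e-6)
})
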