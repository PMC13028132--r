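test_that("non-CV mortality is the min of model-implied and life-table probability", {
  spec <- plain_spec(horizon_years = 28 * 2 / 365.25)  # two cycles
  # life table delivering a per-cycle non-CV cap of exactly 0.005
  ann <- 1 - (1 - 0.005)^(365.25 / 28)
  lt <- validate_life_table(data.frame(
    age = rep(40:110, 2), sex = rep(c("male", "female"), each = 71),
    qx = ifelse(rep(40:110, 2) == 110, 1, ann), cv_fraction = 0
  ))
  s_low <- build_mortality_schedule(cycle_prob(0.001, 28),
                                    cycle_prob(0.002, 28), lt, spec)
  expect_equal(s_low$p_noncv, rep(0.001, 2))  # model 0.001 < cap 0.005
  s_high <- build_mortality_schedule(cycle_prob(0.001, 28),
                                     cycle_prob(0.011, 28), lt, spec)
  expect_equal(s_high$p_noncv, rep(0.005, 2), tolerance = 1e-12)  # capped
})

test_that("cause-deleted life-table arithmetic: qx 0.05 with 40% CV share gives 0.03 non-CV", {
  lt <- validate_life_table(data.frame(
    age = rep(70:110, 2), sex = rep(c("male", "female"), each = 41),
    qx = ifelse(rep(70:110, 2) == 110, 1, 0.05), cv_fraction = 0.4
  ))
  expect_equal(hfmarkov:::life_table_noncv_annual(lt, 72, 0.545), 0.03)
})

test_that("missing attained ages and impossible probability sums raise errors", {
  lt <- synthetic_life_table(min_age = 40, max_age = 80)
  spec <- plain_spec()  # 28-year horizon from age 72 exceeds age 80
  expect_error(
    build_mortality_schedule(cycle_prob(0.001), cycle_prob(0.002), lt, spec),
    "attained age"
  )
  expect_error(
    step_cohort(c(1, 0, 0, 0, 0, 0), diag(4), 0.6, 0.5),
    "exceeds 1"
  )
})

test_that("one cohort step applies deaths first, then KCCQ movement", {
  occ <- c(1, 0, 0, 0, 0, 0)
  expect_equal(step_cohort(occ, diag(4), 0, 0), occ)
  expect_equal(step_cohort(occ, diag(4), 1, 0), c(0, 0, 0, 0, 1, 0))
  expect_equal(step_cohort(occ, diag(4), 0.1, 0.1),
               c(0.8, 0, 0, 0, 0.1, 0.1))
  # survivors are redistributed by the matrix
  P <- matrix(c(0, 1, 0, 0,
                0, 0, 1, 0,
                0, 0, 0, 1,
                0, 0, 0, 1), 4, 4, byrow = TRUE)
  expect_equal(step_cohort(occ, P, 0.5, 0), c(0, 0.5, 0, 0, 0.5, 0))
  expect_error(step_cohort(c(-0.1, 1.1, 0, 0, 0, 0), diag(4), 0, 0),
               "negative")
})

test_that("expected events scale with alive mass and rise with cohort age", {
  m <- event_model("HHF", "control", rate_ref = 0.01, age_coef = 0.02)
  expect_equal(expected_events(c(0, 0, 0, 0, 0.5, 0.5), m, 72), 0)
  m0 <- event_model("HHF", "control", rate_ref = 0.01, age_coef = 0,
                    sex_coef = 0)
  expect_equal(expected_events(0.5, m0, 80), 0.5 * 0.01, tolerance = 1e-12)
  rates <- event_rate_cohort(m, 72 + (0:10), 0.545, default_race_mix())
  expect_true(all(diff(rates) > 0))
})

test_that("discounted and undiscounted life years match the geometric series", {
  p <- 0.012
  n_cyc <- 500
  dy <- 28 / 365.25
  spec <- plain_spec(horizon_years = n_cyc * dy, discount_annual = 0.035)
  tr <- run_cohort(toy_model(p_cv = p, p_noncv = 0, spec = spec), "control")
  s_t <- (1 - p)^(0:n_cyc)
  v_t <- (1 + 0.035)^(-(0:(n_cyc - 1)) * dy)
  ly_expected <- dy * sum((s_t[-length(s_t)] + s_t[-1]) / 2)
  ly_disc_expected <- dy * sum(v_t * (s_t[1:n_cyc] + s_t[2:(n_cyc + 1)]) / 2)
  expect_equal(sum(tr$ly), ly_expected, tolerance = 1e-10)
  expect_equal(sum(tr$ly_disc), ly_disc_expected, tolerance = 1e-10)
  expect_lt(sum(tr$ly_disc), sum(tr$ly))
})

test_that("zero mortality with utility 1 gives LY = QALY = horizon", {
  n_cyc <- 20
  dy <- 28 / 365.25
  spec <- plain_spec(horizon_years = n_cyc * dy,
                     utilities = c(Q1 = 1, Q2 = 1, Q3 = 1, Q4 = 1))
  tr <- run_cohort(toy_model(p_cv = 0, p_noncv = 0, spec = spec), "control")
  expect_equal(sum(tr$ly), n_cyc * dy, tolerance = 1e-12)
  expect_equal(sum(tr$qaly), sum(tr$ly), tolerance = 1e-12)
})

test_that("age-related utility decrement reduces utility by 0.051 after 10 years", {
  dy <- 0.1  # 0.1-year cycles so a cycle starts exactly at 10 elapsed years
  spec <- plain_spec(cycle_days = 0.1 * 365.25, horizon_years = 12,
                     utilities = c(Q1 = 1, Q2 = 1, Q3 = 1, Q4 = 1),
                     age_decrement = -0.0051)
  tr <- run_cohort(toy_model(p_cv = 0, p_noncv = 0, spec = spec), "control")
  i <- which(abs(tr$t0_years - 10) < 1e-9)
  expect_equal(tr$qaly[i], (1 - 0.0051 * 10) * dy, tolerance = 1e-12)
})

test_that("event disutilities subtract one-off QALY decrements per expected event", {
  n_cyc <- 30
  dy <- 28 / 365.25
  base <- plain_spec(horizon_years = n_cyc * dy,
                     utilities = c(Q1 = 1, Q2 = 1, Q3 = 1, Q4 = 1))
  with_dis <- plain_spec(horizon_years = n_cyc * dy,
                         utilities = c(Q1 = 1, Q2 = 1, Q3 = 1, Q4 = 1),
                         event_disutilities = c(HHF = 0.05, UHFV = 0))
  t0 <- run_cohort(toy_model(r_hhf = 0.01, spec = base), "control")
  t1 <- run_cohort(toy_model(r_hhf = 0.01, spec = with_dis), "control")
  expect_equal(sum(t0$qaly) - sum(t1$qaly), 0.05 * sum(t1$events_hhf),
               tolerance = 1e-12)
  expect_equal(t0$events_hhf, t1$events_hhf)
})

test_that("full 28-year trace conserves mass, keeps deaths monotone and discounting coherent", {
  spec <- model_spec()  # full defaults: AE basket, disutilities, decrement
  lt <- synthetic_life_table()
  m <- toy_model(p_cv = 0.002, p_noncv = 0.0015, r_hhf = 0.007,
                 r_uhfv = 0.0012, spec = spec, life_table = lt)
  tr <- run_cohort(m, "control")
  expect_equal(nrow(tr), 366)
  occ <- as.matrix(tr[, c("Q1", "Q2", "Q3", "Q4", "CV_death", "nonCV_death")])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
  expect_true(all(diff(tr$CV_death) >= 0))
  expect_true(all(diff(tr$nonCV_death) >= 0))
  expect_true(all(diff(tr$cum_ly) > 0))
  expect_true(all(diff(tr$cum_qaly) > 0))
  expect_lte(sum(tr$ly_disc), sum(tr$ly))
  expect_lte(sum(tr$qaly), sum(tr$ly))  # utilities <= 1
})

test_that("engine expectations match an individual-level microsimulation", {
  P <- default_kccq_dynamics()
  p_cv <- 0.004; p_ncv <- 0.003; r_hhf <- 0.02; r_uhfv <- 0.005
  utilities <- c(Q1 = 0.64, Q2 = 0.74, Q3 = 0.81, Q4 = 0.86)
  n_cyc <- 26
  dy <- 28 / 365.25
  start <- c(0.2395, 0.2615, 0.2455, 0.2535)
  spec <- plain_spec(horizon_years = n_cyc * dy, utilities = utilities)
  tr <- run_cohort(toy_model(p_cv, p_ncv, r_hhf, r_uhfv, spec = spec), "control")
  eng <- list(ly = sum(tr$ly), qaly = sum(tr$qaly), hhf = sum(tr$events_hhf),
              uhfv = sum(tr$events_uhfv),
              cv = tr$CV_death[n_cyc], ncv = tr$nonCV_death[n_cyc])
  mc <- microsim_oracle(100000, n_cyc, P, p_cv, p_ncv, r_hhf, r_uhfv,
                        utilities, start, dy, seed = 99)
  expect_lt(abs(eng$ly - mc$ly["mean"]), 3 * mc$ly["se"])
  expect_lt(abs(eng$qaly - mc$qaly["mean"]), 3 * mc$qaly["se"])
  expect_lt(abs(eng$hhf - mc$hhf["mean"]), 3 * mc$hhf["se"])
  expect_lt(abs(eng$uhfv - mc$uhfv["mean"]), 3 * mc$uhfv["se"])
  expect_lt(abs(eng$cv - mc$cv_deaths["mean"]), 3 * mc$cv_deaths["se"])
  expect_lt(abs(eng$ncv - mc$noncv_deaths["mean"]), 3 * mc$noncv_deaths["se"])
})

test_that("active-arm trace blends risk sets by the discontinuation curve", {
  dy <- 28 / 365.25
  spec <- plain_spec(horizon_years = 50 * dy)
  # active arm protective for CV death; immediate-ish discontinuation washes
  # the effect out towards control
  act <- const_arm(0.002, 0.005, 0.006, 0.001, arm = "active")
  ctl <- const_arm(0.004, 0.007, 0.008, 0.0015, arm = "control")
  m_on <- hf_model(spec, act, ctl, NULL, discontinuation = NULL)
  m_off <- hf_model(spec, act, ctl, NULL,
                    discontinuation = cycle_prob(0.5, 28))
  s_on <- trace_summary(run_cohort(m_on, "active"))
  s_off <- trace_summary(run_cohort(m_off, "active"))
  s_ctl <- trace_summary(run_cohort(m_on, "control"))
  expect_lt(s_on$cv_deaths, s_off$cv_deaths)   # staying on treatment protects
  expect_lt(s_off$cv_deaths, s_ctl$cv_deaths)  # but still better than control
  # control arm is untouched by the discontinuation input
  expect_identical(run_cohort(m_on, "control"), run_cohort(m_off, "control"))
})

test_that("cumulative outcomes interpolate between cycle boundaries", {
  dy <- 28 / 365.25
  spec <- plain_spec(horizon_years = 40 * dy)
  tr <- run_cohort(toy_model(p_cv = 0.004, p_noncv = 0, r_hhf = 0.01,
                             spec = spec), "control")
  at <- events_at(tr, 29)
  k <- (29 / 12) / dy  # 31.52 cycles
  lo <- floor(k); frac <- k - lo
  expect_equal(at$hhf,
               tr$cum_hhf[lo] + frac * (tr$cum_hhf[lo + 1] - tr$cum_hhf[lo]),
               tolerance = 1e-12)
  expect_error(events_at(run_cohort(toy_model(spec = plain_spec(
    horizon_years = 5 * dy)), "control"), 29), "shorter")
})
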