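#' @importFrom survival Surv
NULL

SURV_FAMILIES <- c(
  exponential = "exp",
  weibull = "weibull",
  lognormal = "lnorm",
  loglogistic = "llogis",
  gompertz = "gompertz",
  generalised_gamma = "gengamma"
)

#' Fit a parametric survival model
#'
#' Maximum-likelihood fit of one of six parametric time-to-event families
#' (exponential, Weibull, log-normal, log-logistic, Gompertz, generalised
#' gamma) to right-censored data, as used for extrapolating cardiovascular
#' and all-cause mortality and treatment discontinuation over the model
#' horizon. Fitting is delegated to [flexsurv::flexsurvreg()]; AIC and BIC
#' are recomputed from the log-likelihood.
#'
#' @param time positive event/censoring times (years recommended: the cohort
#'   engine evaluates fitted curves on a time-in-years axis).
#' @param status 1 = event, 0 = censored.
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"generalised_gamma"`.
#' @param endpoint label: `"CV_death"`, `"all_cause_death"` or
#'   `"discontinuation"`.
#' @return An object of class `hf_survival_fit` with elements `family`,
#'   `parameters` (natural scale), `log_likelihood`, `aic`, `bic`, `n`, `k`,
#'   `endpoint`.
#' @export
fit_parametric_survival <- function(time, status,
                                    family = names(SURV_FAMILIES),
                                    endpoint = c("discontinuation", "CV_death",
                                                 "all_cause_death")) {
  family <- match.arg(family)
  endpoint <- match.arg(endpoint)
  stopifnot(length(time) == length(status))
  if (any(time <= 0)) stop("times must be positive")
  if (sum(status) < 1) stop("estimation failure: all observations censored")
  dist <- SURV_FAMILIES[[family]]
  fit <- flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1, dist = dist)
  k <- nrow(fit$res)
  ll <- fit$loglik
  n <- length(time)
  structure(
    list(
      family = family, dist = dist,
      parameters = stats::setNames(fit$res[, "est"], rownames(fit$res)),
      log_likelihood = ll,
      aic = -2 * ll + 2 * k,
      bic = -2 * ll + k * log(n),
      n = n, k = k, endpoint = endpoint
    ),
    class = "hf_survival_fit"
  )
}

#' Fit several survival families to the same data
#'
#' Families whose optimisation fails (a known possibility for the generalised
#' gamma on awkward data) are dropped with a warning rather than aborting the
#' comparison.
#'
#' @inheritParams fit_parametric_survival
#' @param families subset of the six supported family names.
#' @return List of `hf_survival_fit` objects (possibly shorter than
#'   `families`).
#' @export
fit_survival_families <- function(time, status, families = names(SURV_FAMILIES),
                                  endpoint = "discontinuation") {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(
      fit_parametric_survival(time, status, fam, endpoint),
      error = function(e) {
        warning("family ", fam, " failed to fit: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no survival family could be fitted")
  fits
}

#' Select the best-fitting survival family
#'
#' Returns the fit minimising the information criterion. Fits within 2
#' criterion units of the minimum are treated as statistically equivalent and
#' the most parsimonious (fewest parameters) among them is preferred; within
#' that set the smallest criterion wins.
#'
#' @param fits list of `hf_survival_fit` objects for the same endpoint/data.
#' @param criterion "AIC" or "BIC".
#' @return The selected `hf_survival_fit`.
#' @export
select_best_fit <- function(fits, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("no fits supplied")
  ep <- vapply(fits, function(f) f$endpoint, character(1))
  if (length(unique(ep)) > 1L) stop("fits mix endpoints: ", paste(unique(ep), collapse = ", "))
  crit <- vapply(fits, function(f) if (criterion == "AIC") f$aic else f$bic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  near <- which(crit <= min(crit) + 2)
  best <- near[order(k[near], crit[near])][1]
  fits[[best]]
}

#' Survival function of a fitted parametric model
#'
#' @param fit an `hf_survival_fit`.
#' @param t times (same unit as the fitting data) at which S(t) is required.
#' @return Survival probabilities, monotone non-increasing from 1.
#' @export
survival_prob <- function(fit, t) {
  stopifnot(inherits(fit, "hf_survival_fit"), all(t >= 0))
  pfun <- switch(fit$dist,
    exp = stats::pexp, weibull = stats::pweibull, lnorm = stats::plnorm,
    llogis = flexsurv::pllogis, gompertz = flexsurv::pgompertz,
    gengamma = flexsurv::pgengamma
  )
  args <- c(list(q = t), as.list(fit$parameters), list(lower.tail = FALSE))
  do.call(pfun, args)
}

#' @export
print.hf_survival_fit <- function(x, ...) {
  cat("<hf_survival_fit>", x$family, "for", x$endpoint,
      sprintf("(n=%d, logLik=%.2f, AIC=%.2f, BIC=%.2f)\n",
              x$n, x$log_likelihood, x$aic, x$bic))
  print(round(x$parameters, 6))
  invisible(x)
}

#' Constant per-cycle probability
#'
#' A probability attached to the cycle length it was derived on, so the
#' engine can re-express it on a different cycle grid via the constant-hazard
#' relation `1 - (1 - p)^(target/source)`.
#'
#' @param value probability in \[0, 1\].
#' @param cycle_days length of the cycle the probability refers to.
#' @param source optional note on how the value was obtained.
#' @return Object of class `hf_cycle_prob`.
#' @export
cycle_prob <- function(value, cycle_days = 28, source = "constant") {
  stopifnot_prob(value, "value")
  stopifnot(cycle_days > 0)
  structure(list(value = value, cycle_days = cycle_days, source = source),
            class = "hf_cycle_prob")
}

#' Convert an event rate to a per-cycle probability
#'
#' Uses the constant-hazard (exponential) transform
#' `p = 1 - exp(-(rate/100) * cycle_years)`. For example a cardiovascular
#' mortality rate of 3.56 per 100 person-years converts to a monthly
#' (365.25/12-day) probability of 0.0030 at four decimal places.
#'
#' @param rate events per 100 person-years, non-negative.
#' @param cycle_days target cycle length in days (default one month).
#' @return An `hf_cycle_prob`; its `value` carries full precision, rounding
#'   is the caller's choice.
#' @export
rate_to_cycle_probability <- function(rate, cycle_days = MONTH_DAYS) {
  if (rate < 0) stop("rate must be non-negative")
  stopifnot(cycle_days > 0)
  p <- 1 - exp(-(rate / 100) * cycle_days / DAYS_PER_YEAR)
  cycle_prob(p, cycle_days, source = sprintf("rate %.4g per 100 PY", rate))
}

#' Convert an observed event proportion to a per-cycle probability
#'
#' Spreads a proportion observed over the follow-up window uniformly over
#' cycles assuming a constant risk: `p = 1 - (1 - proportion)^(cycle/followup)`.
#' Used to turn trial adverse-event shares into per-cycle probabilities.
#'
#' @param proportion observed share in \[0, 1).
#' @param followup_days follow-up window (e.g. median follow-up) in days.
#' @param cycle_days model cycle length in days.
#' @return An `hf_cycle_prob`.
#' @export
proportion_to_cycle_probability <- function(proportion, followup_days,
                                            cycle_days = 28) {
  if (proportion < 0 || proportion >= 1) stop("proportion must lie in [0, 1)")
  if (followup_days < cycle_days || cycle_days <= 0) {
    stop("follow-up must be at least one cycle long")
  }
  p <- 1 - (1 - proportion)^(cycle_days / followup_days)
  cycle_prob(p, cycle_days, source = sprintf("proportion %.4g over %.4g days",
                                             proportion, followup_days))
}

# conditional probability of the event in (t0, t1] given survival to t0,
# for either a parametric fit or a constant per-cycle probability
cond_event_prob <- function(x, t0_years, t1_years) {
  stopifnot(t1_years > t0_years)
  if (inherits(x, "hf_survival_fit")) {
    s0 <- survival_prob(x, t0_years)
    s1 <- survival_prob(x, t1_years)
    ifelse(s0 < 1e-300, 1, pmin(pmax(1 - s1 / s0, 0), 1))
  } else if (inherits(x, "hf_cycle_prob")) {
    n_cycles <- (t1_years - t0_years) * DAYS_PER_YEAR / x$cycle_days
    1 - (1 - x$value)^n_cycles
  } else {
    stop("expected an hf_survival_fit or hf_cycle_prob")
  }
}

#' Estimate a KCCQ quartile transition matrix
#'
#' Counts quartile-to-quartile moves between consecutive assessments in a
#' longitudinal KCCQ panel and row-normalises the counts. A quartile never
#' observed as a starting state yields an identity row (with a warning), so
#' the matrix stays row-stochastic.
#'
#' @param kccq data.frame with columns `patient_id`, `time_days`, `score`
#'   (assessments at roughly 30-day intervals).
#' @param bounds KCCQ band edges, see [kccq_bounds()].
#' @return 4x4 row-stochastic matrix (rows/cols Q1..Q4).
#' @export
estimate_transition_matrix <- function(kccq, bounds = kccq_bounds()) {
  stopifnot(all(c("patient_id", "time_days", "score") %in% names(kccq)))
  if (!nrow(kccq)) stop("empty KCCQ panel")
  kccq <- kccq[order(kccq$patient_id, kccq$time_days), ]
  band <- kccq_band(kccq$score, bounds)
  id <- kccq$patient_id
  same <- id[-1] == id[-length(id)]
  from <- band[-length(band)][same]
  to <- band[-1][same]
  if (!length(from)) stop("need at least one panel with >= 2 assessments")
  counts <- matrix(0, 4, 4, dimnames = list(paste0("Q", 1:4), paste0("Q", 1:4)))
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  rs <- rowSums(counts)
  m <- counts
  for (r in 1:4) {
    if (rs[r] == 0) {
      warning("no observed transitions out of Q", r, "; using identity row")
      m[r, ] <- 0
      m[r, r] <- 1
    } else {
      m[r, ] <- counts[r, ] / rs[r]
    }
  }
  m
}

#' Fit the marginal recurrent-event model
#'
#' Fits the per-cycle expected event count as a log-linear (Poisson, log
#' link) model in baseline age, sex and race with a log-exposure offset, the
#' marginal (GEE-type) specification used for recurrent HHF/UHFV counts.
#' Counts are aggregated per patient over their time at risk; because the
#' covariates are constant within patient, the marginal point estimates do
#' not depend on the working correlation.
#'
#' Covariate levels absent from the data are dropped with a warning (their
#' contrasts are set to zero). If no events occurred at all, a zero-rate
#' model is returned with `zero_rate = TRUE` rather than a degenerate
#' intercept.
#'
#' @param trial an `hf_trial` (see [generate_trial()]), or a list with
#'   `patients` and `events` data.frames in the same layout.
#' @param event_type "HHF" or "UHFV".
#' @param arm "active" or "control".
#' @param cycle_days cycle length the fitted per-cycle rate refers to.
#' @return An `hf_event_model` with robust coefficient container and
#'   variance matrix for the estimated contrasts.
#' @export
fit_event_gee <- function(trial, event_type = c("HHF", "UHFV"),
                          arm = c("active", "control"), cycle_days = 28) {
  event_type <- match.arg(event_type)
  arm <- match.arg(arm)
  pts <- trial$patients[trial$patients$arm == arm, ]
  if (!nrow(pts)) stop("no patients in arm ", arm)
  end <- pmin(pts$censor_time, ifelse(is.na(pts$death_time), Inf, pts$death_time))
  exposure <- end / cycle_days
  if (sum(exposure) <= 0) stop("zero total exposure")
  ev <- trial$events[trial$events$event_type == event_type, ]
  n_ev <- ev[ev$patient_id %in% pts$patient_id, ]
  count <- as.integer(table(factor(n_ev$patient_id, levels = pts$patient_id)))
  if (any(count < 0)) stop("negative event counts")
  if (sum(count) == 0) {
    return(new_event_model(event_type, arm,
                           c(intercept = -Inf, age = 0, sexmale = 0,
                             raceAsian = 0, raceBlack = 0, raceOther = 0),
                           cycle_days, zero_rate = TRUE))
  }
  dat <- data.frame(
    count = count,
    age = pts$age_baseline,
    sex = factor(pts$sex, levels = c("female", "male")),
    race = factor(pts$race, levels = c("White", "Asian", "Black", "Other")),
    exposure = exposure
  )
  dat <- dat[dat$exposure > 0, ]
  dropped <- character()
  terms <- "age"
  if (nlevels(droplevels(dat$sex)) > 1L) terms <- c(terms, "sex") else {
    dropped <- c(dropped, "sex")
  }
  if (nlevels(droplevels(dat$race)) > 1L) terms <- c(terms, "race") else {
    dropped <- c(dropped, "race")
  }
  if (length(dropped)) {
    warning("covariate level(s) absent; dropping: ", paste(dropped, collapse = ", "))
    dat$sex <- droplevels(dat$sex)
    dat$race <- droplevels(dat$race)
  }
  form <- stats::as.formula(paste("count ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(form, family = stats::poisson(),
                    offset = log(exposure), data = dat)
  cf <- stats::coef(fit)
  std <- c(intercept = unname(cf["(Intercept)"]),
           age = unname(cf["age"]),
           sexmale = if ("sexmale" %in% names(cf)) unname(cf["sexmale"]) else 0,
           raceAsian = if ("raceAsian" %in% names(cf)) unname(cf["raceAsian"]) else 0,
           raceBlack = if ("raceBlack" %in% names(cf)) unname(cf["raceBlack"]) else 0,
           raceOther = if ("raceOther" %in% names(cf)) unname(cf["raceOther"]) else 0)
  new_event_model(event_type, arm, std, cycle_days,
                  vcov = stats::vcov(fit), dropped = dropped)
}
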