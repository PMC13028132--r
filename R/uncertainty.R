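#' Parameter distribution for sensitivity analysis
#'
#' Describes one uncertain model input: where it lives inside an
#' [hf_model()] (a `/`-separated path of list names, e.g.
#' `"spec/utilities/Q1"` or `"arms/control/transition"` with `row` set for a
#' Dirichlet transition row), the sampling family for probabilistic
#' sensitivity analysis, and deterministic low/high bounds for one-way
#' analysis. Families follow standard health-economic practice: beta for
#' probabilities and utilities, gamma or log-normal for rates, Dirichlet for
#' transition-matrix rows, `fixed` for parameters held at base value.
#'
#' @param path character path into the model object.
#' @param family one of "fixed", "beta", "gamma", "normal", "lognormal",
#'   "dirichlet".
#' @param par1,par2 family hyperparameters (beta: shape1/shape2, gamma:
#'   shape/rate, normal: mean/sd, lognormal: meanlog/sdlog).
#' @param alpha Dirichlet concentration vector (length 4 for a transition
#'   row).
#' @param dsa_low,dsa_high deterministic bounds (scalar, or length-4 row for
#'   dirichlet paths); `dsa_low <= dsa_high` element-wise.
#' @param row transition-matrix row index for dirichlet paths.
#' @param name display label (defaults to the path).
#' @return Object of class `hf_param_dist`.
#' @export
param_dist <- function(path,
                       family = c("fixed", "beta", "gamma", "normal",
                                  "lognormal", "dirichlet"),
                       par1 = NULL, par2 = NULL, alpha = NULL,
                       dsa_low = NULL, dsa_high = NULL, row = NULL,
                       name = path) {
  family <- match.arg(family)
  if (family == "dirichlet") {
    if (is.null(alpha) || any(alpha <= 0)) stop("dirichlet needs positive alpha")
    if (is.null(row)) stop("dirichlet paths need a transition row index")
  } else if (family != "fixed") {
    if (is.null(par1) || is.null(par2)) stop(family, " needs par1 and par2")
    if (family %in% c("beta", "gamma") && (par1 <= 0 || par2 <= 0)) {
      stop(family, " hyperparameters must be positive")
    }
    if (family == "normal" && par2 < 0) stop("normal sd must be non-negative")
    if (family == "lognormal" && par2 < 0) stop("lognormal sdlog must be non-negative")
  }
  if (is.numeric(dsa_low) && is.numeric(dsa_high) && any(dsa_low > dsa_high)) {
    stop("dsa_low must not exceed dsa_high")
  }
  structure(list(path = path, family = family, par1 = par1, par2 = par2,
                 alpha = alpha, dsa_low = dsa_low, dsa_high = dsa_high,
                 row = row, name = name),
            class = "hf_param_dist")
}

split_path <- function(path) strsplit(path, "/", fixed = TRUE)[[1]]

get_param <- function(model, dist) {
  x <- model[[split_path(dist$path)]]
  if (!is.null(dist$row)) x[dist$row, ] else x
}

set_param <- function(model, dist, value) {
  p <- split_path(dist$path)
  if (!is.null(dist$row)) {
    m <- model[[p]]
    m[dist$row, ] <- value
    value <- m
  }
  model[[p]] <- value
  model
}

draw_param <- function(dist, base) {
  switch(dist$family,
    fixed = base,
    beta = stats::rbeta(1, dist$par1, dist$par2),
    gamma = stats::rgamma(1, dist$par1, rate = dist$par2),
    normal = stats::rnorm(1, dist$par1, dist$par2),
    lognormal = stats::rlnorm(1, dist$par1, dist$par2),
    dirichlet = {
      g <- stats::rgamma(length(dist$alpha), dist$alpha)
      g / sum(g)
    }
  )
}

default_outcome_fn <- function(model) {
  out <- c()
  for (a in c("active", "control")) {
    s <- trace_summary(run_cohort(model, a))
    v <- c(ly = s$ly, ly_disc = s$ly_disc, qaly_disc = s$qaly_disc,
           cv_deaths = s$cv_deaths, hhf = s$hhf, uhfv = s$uhfv)
    names(v) <- paste0(names(v), "_", a)
    out <- c(out, v)
  }
  out
}

#' Deterministic one-way sensitivity analysis (tornado)
#'
#' Varies each parameter alone between its deterministic bounds, holding all
#' others at base values, and reports the resulting outcome swing, sorted by
#' descending range.
#'
#' @param model an `hf_model`.
#' @param dists list of [param_dist()] objects with `dsa_low`/`dsa_high`
#'   set (parameters without bounds are skipped).
#' @param outcome_fn function(model) -> scalar outcome; the default is the
#'   control-arm discounted QALY total.
#' @return data.frame `parameter`, `low_result`, `high_result`, `range`,
#'   sorted by descending `range`.
#' @export
run_dsa <- function(model, dists,
                    outcome_fn = function(m) trace_summary(run_cohort(m, "control"))$qaly_disc) {
  dists <- Filter(function(d) !is.null(d$dsa_low) && !is.null(d$dsa_high), dists)
  if (!length(dists)) stop("no parameter carries deterministic bounds")
  rows <- lapply(dists, function(d) {
    lo <- outcome_fn(set_param(model, d, d$dsa_low))
    hi <- outcome_fn(set_param(model, d, d$dsa_high))
    data.frame(parameter = d$name, low_result = lo, high_result = hi,
               range = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Runs the model `n_iter` times with all uncertain parameters redrawn from
#' their distributions each iteration. Each iteration uses its own RNG
#' substream derived from the master seed, so results do not depend on
#' evaluation order. Summaries are means with 2.5/97.5 percentile intervals.
#'
#' @param model an `hf_model`.
#' @param dists list of [param_dist()] objects.
#' @param n_iter iterations (the reference analysis uses 1000).
#' @param seed master seed.
#' @param outcome_fn function(model) -> named numeric vector of outcomes;
#'   default records LY, discounted LY/QALY, CV deaths, HHF and UHFV per arm.
#' @param keep_iterations retain the per-iteration outcome table?
#' @return Object of class `hf_psa`: `summary` (outcome, mean, lo, hi),
#'   optionally `iterations`, plus `n_iter` and `seed`.
#' @export
run_psa <- function(model, dists, n_iter = 1000, seed = 1L,
                    outcome_fn = default_outcome_fn, keep_iterations = TRUE) {
  stopifnot(n_iter >= 1)
  iters <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    m <- with_seed(seed + i, {
      mi <- model
      for (d in dists) {
        mi <- set_param(mi, d, draw_param(d, get_param(model, d)))
      }
      mi
    })
    iters[[i]] <- outcome_fn(m)
  }
  mat <- do.call(rbind, iters)
  summ <- data.frame(
    outcome = colnames(mat),
    mean = colMeans(mat),
    lo = apply(mat, 2, stats::quantile, probs = 0.025, names = FALSE),
    hi = apply(mat, 2, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 iterations = if (keep_iterations) as.data.frame(mat) else NULL,
                 n_iter = n_iter, seed = seed),
            class = "hf_psa")
}

#' Outcome function recording counts at a validation window
#'
#' Builds an outcome function for [run_psa()] that records CV deaths, HHF
#' and UHFV per cohort member for both arms at `months` (interpolated on
#' the cycle grid), the quantities compared against trial counts.
#'
#' @param months window in calendar months.
#' @return function(model) -> named numeric vector.
#' @export
validation_outcome_fn <- function(months = 29) {
  function(model) {
    out <- c()
    for (a in c("active", "control")) {
      at <- events_at(run_cohort(model, a), months)
      v <- c(cv_deaths = at$cv_deaths, hhf = at$hhf, uhfv = at$uhfv)
      names(v) <- paste0(names(v), "_", a)
      out <- c(out, v)
    }
    out
  }
}

#' Compare PSA means with trial counts
#'
#' Applies the external-validation difference definitions to the PSA mean
#' event counts (scaled to the trial arm sizes), flagging whether each
#' relative deviation is below 20%.
#'
#' @param psa an `hf_psa` whose outcomes include `cv_deaths_*`, `hhf_*`,
#'   `uhfv_*` per cohort member for both arms.
#' @param trial_counts data.frame `outcome`, `arm`, `count`.
#' @param arm_n named arm sizes `c(active=, control=)`.
#' @return An `hf_validation_report` with an extra `within_20pct` column.
#' @export
summarize_psa <- function(psa, trial_counts, arm_n = c(active = 3000, control = 3000)) {
  stopifnot(inherits(psa, "hf_psa"))
  mean_of <- function(nm) {
    v <- psa$summary$mean[psa$summary$outcome == nm]
    if (!length(v)) stop("PSA outcomes lack ", nm)
    v
  }
  model_counts <- do.call(rbind, lapply(c("active", "control"), function(a) {
    data.frame(outcome = c("CV_deaths", "HHF", "UHFV"), arm = a,
               count = scale_to_trial(
                 c(mean_of(paste0("cv_deaths_", a)),
                   mean_of(paste0("hhf_", a)),
                   mean_of(paste0("uhfv_", a))), arm_n[[a]]),
               stringsAsFactors = FALSE)
  }))
  rep <- external_validation(model_counts, trial_counts)
  rep$within_20pct <- !is.na(rep$relative_difference) & rep$relative_difference < 20
  rep
}
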