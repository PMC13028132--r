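# Individual-level microsimulation oracle for the cohort engine.
#
# Simulates n subjects under the same per-cycle probabilities the engine
# uses: deaths first (one uniform split CV / non-CV), survivors move among
# the four KCCQ states by the transition matrix. Life years and QALYs use
# the same mid-cycle convention as the engine: a subject alive through the
# cycle accrues a full cycle, a subject dying during it accrues half; state
# utility is averaged between cycle start and cycle end (0 when dead).
# Events are Poisson with the full per-cycle rate for survivors and half the
# rate for subjects dying that cycle.
microsim_oracle <- function(n, n_cycles, P, p_cv, p_noncv,
                            r_hhf, r_uhfv, utilities, start_occ, dy, seed) {
  set.seed(seed)
  state <- sample.int(4L, n, replace = TRUE, prob = start_occ)
  ly <- numeric(n); qaly <- numeric(n)
  hhf <- integer(n); uhfv <- integer(n)
  cum <- t(apply(P, 1, cumsum))
  u6 <- c(utilities, 0, 0)
  for (t in seq_len(n_cycles)) {
    alive <- state <= 4L
    if (!any(alive)) break
    u <- stats::runif(n)
    die_cv <- alive & u < p_cv
    die_ncv <- alive & !die_cv & u < p_cv + p_noncv
    died <- die_cv | die_ncv
    surv <- alive & !died
    state_start <- state
    # survivors transition
    if (any(surv)) {
      r <- stats::runif(sum(surv))
      state[surv] <- 1L + rowSums(r > cum[state[surv], , drop = FALSE] + 1e-15)
    }
    state[die_cv] <- 5L
    state[die_ncv] <- 6L
    ly <- ly + dy * (surv + 0.5 * died)
    qaly <- qaly + dy * (u6[state_start] * alive + u6[state] * (state <= 4L)) / 2
    n_ev_h <- stats::rpois(n, r_hhf * (surv + 0.5 * died))
    n_ev_u <- stats::rpois(n, r_uhfv * (surv + 0.5 * died))
    hhf <- hhf + n_ev_h
    uhfv <- uhfv + n_ev_u
  }
  mean_se <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(n))
  list(
    ly = mean_se(ly), qaly = mean_se(qaly),
    hhf = mean_se(hhf), uhfv = mean_se(uhfv),
    cv_deaths = mean_se(state == 5L), noncv_deaths = mean_se(state == 6L)
  )
}

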