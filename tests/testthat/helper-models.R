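# Builders for small engine configurations used across tests.

# Per-arm inputs with constant per-cycle probabilities and intercept-only
# event rates (age/sex/race coefficients zero).
const_arm <- function(p_cv, p_allcause, r_hhf = 0, r_uhfv = 0,
                      P = default_kccq_dynamics(), cycle_days = 28,
                      arm = "control") {
  arm_inputs(
    P,
    cycle_prob(p_cv, cycle_days),
    cycle_prob(p_allcause, cycle_days),
    list(HHF = event_model("HHF", arm, r_hhf, age_coef = 0, sex_coef = 0,
                           cycle_days = cycle_days),
         UHFV = event_model("UHFV", arm, r_uhfv, age_coef = 0, sex_coef = 0,
                            cycle_days = cycle_days))
  )
}

# A plain spec without AE basket or event disutilities, for clean arithmetic.
plain_spec <- function(...) {
  defaults <- list(
    ae = data.frame(), event_disutilities = c(HHF = 0, UHFV = 0),
    age_decrement = 0, discount_annual = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_spec, args)
}

# Model with identical constant-probability arms.
toy_model <- function(p_cv = 0.004, p_noncv = 0.002, r_hhf = 0.006,
                      r_uhfv = 0.001, spec = plain_spec(),
                      P = default_kccq_dynamics(),
                      life_table = NULL, discontinuation = NULL) {
  # the engine derives p_noncv as p_allcause - p_cv; invert that here
  p_ac <- p_cv + p_noncv
  a <- const_arm(p_cv, p_ac, r_hhf, r_uhfv, P, spec$cycle_days, "active")
  c_ <- const_arm(p_cv, p_ac, r_hhf, r_uhfv, P, spec$cycle_days, "control")
  hf_model(spec, a, c_, life_table, discontinuation)
}
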