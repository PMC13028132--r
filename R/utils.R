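# Shared constants and small helpers.

DAYS_PER_YEAR <- 365.25
MONTH_DAYS <- 365.25 / 12

#' KCCQ quartile bounds
#'
#' Lower-closed cut points defining the four KCCQ total-summary-score health
#' states: Q1 \[1, 50), Q2 \[50, 69.8), Q3 \[69.8, 87.5), Q4 \[87.5, 100].
#' The bounds derive from the baseline quartiles of the pivotal trial
#' population and are held fixed over the model horizon.
#'
#' @return Numeric vector of length 5 (band edges).
#' @export
kccq_bounds <- function() c(1, 50, 69.8, 87.5, 100)

#' Assign KCCQ scores to quartile states
#'
#' @param score numeric KCCQ TSS values in \[1, 100].
#' @param bounds band edges as returned by [kccq_bounds()].
#' @return Integer band 1..4 (Q1..Q4); bands are lower-closed, so a score of
#'   exactly 50 falls in Q2, 69.8 in Q3, 87.5 in Q4.
#' @export
kccq_band <- function(score, bounds = kccq_bounds()) {
  stopifnot(is.numeric(score))
  if (any(score < bounds[1] - 1e-9 | score > bounds[5] + 1e-9, na.rm = TRUE)) {
    stop("KCCQ scores must lie in [", bounds[1], ", ", bounds[5], "]")
  }
  findInterval(score, bounds[2:4]) + 1L
}

# round-half-up (base round() is round-half-even); used only at presentation
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_prob <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must contain probabilities in [0, 1]")
  }
  invisible(x)
}

assert_mix <- function(p, name = deparse(substitute(p)), tol = 1e-9) {
  stopifnot_prob(p, name)
  if (abs(sum(p) - 1) > tol) stop(name, " must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

assert_row_stochastic <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("transition matrix must be square")
  if (any(m < -1e-12)) stop("transition matrix has negative entries")
  if (any(abs(rowSums(m) - 1) > tol)) stop("transition matrix rows must sum to 1")
  invisible(m)
}
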