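#' Synthetic national life table
#'
#' Builds a synthetic life table of age- and sex-specific annual death
#' probabilities (qx) with an accompanying fraction of deaths attributable to
#' cardiovascular causes. Annual mortality follows a Gompertz-Makeham hazard
#' mu(age) = a + b * exp(c * age), with per-sex parameters chosen to give
#' plausible general-population magnitudes (qx of roughly 0.005 at age 60 and
#' 0.15 at age 95 for males, females slightly lower). The CV fraction rises
#' gently with age around one quarter of all deaths.
#'
#' This is a stand-in for a national (e.g. UK) life table, which cannot be
#' redistributed here; magnitudes are realistic but the table is synthetic.
#'
#' @param min_age,max_age integer age range; `qx` is forced to 1 at `max_age`
#'   so the table closes out.
#' @return A data.frame with columns `age`, `sex` ("male"/"female"), `qx`,
#'   `cv_fraction`, of class `hf_life_table`.
#' @export
synthetic_life_table <- function(min_age = 40L, max_age = 110L) {
  stopifnot(min_age < max_age)
  ages <- seq.int(min_age, max_age)
  gm <- function(a, b, cc) {
    h <- a + b * exp(cc * ages)
    1 - exp(-h)
  }
  qx_m <- gm(5e-4, 2.8e-5, 0.092)
  qx_f <- gm(3e-4, 1.6e-5, 0.096)
  qx_m[ages == max_age] <- 1
  qx_f[ages == max_age] <- 1
  cvf <- pmin(0.22 + 0.0015 * pmax(ages - 40, 0), 0.35)
  lt <- data.frame(
    age = rep(ages, 2L),
    sex = rep(c("male", "female"), each = length(ages)),
    qx = c(pmin(qx_m, 1), pmin(qx_f, 1)),
    cv_fraction = rep(cvf, 2L),
    stringsAsFactors = FALSE
  )
  validate_life_table(lt)
}

#' Read a life table from CSV
#'
#' Expected columns: `age` (integer years), `sex` ("male"/"female"), `qx`
#' (annual death probability), `cv_fraction` (share of deaths from CV causes,
#' used to derive cause-deleted non-CV mortality).
#'
#' @param path CSV file path.
#' @return Validated `hf_life_table` data.frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt)
}

#' Validate a life table
#'
#' Checks column layout, probability ranges, age contiguity within sex and
#' closure (terminal age with `qx = 1`).
#'
#' @param lt data.frame with columns `age`, `sex`, `qx`, `cv_fraction`.
#' @return The table, classed `hf_life_table`.
#' @export
validate_life_table <- function(lt) {
  req <- c("age", "sex", "qx", "cv_fraction")
  if (!all(req %in% names(lt))) {
    stop("life table must have columns: ", paste(req, collapse = ", "))
  }
  stopifnot_prob(lt$qx, "qx")
  stopifnot_prob(lt$cv_fraction, "cv_fraction")
  for (s in unique(lt$sex)) {
    a <- sort(lt$age[lt$sex == s])
    if (any(diff(a) != 1L)) stop("life table ages must be contiguous within sex")
    if (lt$qx[lt$sex == s & lt$age == max(a)] != 1) {
      stop("terminal age must have qx = 1")
    }
  }
  class(lt) <- c("hf_life_table", "data.frame")
  lt
}

# Sex-weighted annual non-CV death probability at an integer attained age.
# Deaths from CV causes are deleted via qx * (1 - cv_fraction) so that the cap
# does not double-count CV mortality modelled separately.
life_table_noncv_annual <- function(lt, age, male_fraction) {
  age <- as.integer(floor(age))
  out <- numeric(length(age))
  for (i in seq_along(age)) {
    rows <- lt[lt$age == age[i], ]
    if (nrow(rows) == 0L) {
      stop("life table does not cover attained age ", age[i])
    }
    qm <- rows$qx[rows$sex == "male"]
    qf <- rows$qx[rows$sex == "female"]
    cm <- rows$cv_fraction[rows$sex == "male"]
    cf <- rows$cv_fraction[rows$sex == "female"]
    if (!length(qm) || !length(qf)) stop("life table needs both sexes at age ", age[i])
    out[i] <- male_fraction * qm * (1 - cm) + (1 - male_fraction) * qf * (1 - cf)
  }
  out
}
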