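#' Build a Gompertz-Makeham life table
#'
#' Generates an annual life table from the Gompertz-Makeham law of mortality,
#' in which the force of mortality at age \eqn{x} is \eqn{a + b c^x}: a
#' constant background hazard `a` plus a senescent component growing
#' geometrically with age. The annual death probability is
#' \eqn{q(x) = 1 - \exp\{-(a + b c^x)\}} for every age except the terminal
#' one, where \eqn{q = 1} so the table closes out.
#'
#' These tables stand in for a national period life table (the model's
#' mortality input); they are synthetic, not a reproduction of any published
#' table. The packaged defaults (see [synthetic_life_table()]) are calibrated
#' to sex-specific life expectancies similar to Brazil in the mid-2010s.
#'
#' @param a Background (age-independent) hazard per year; `a >= 0`.
#' @param b Senescent hazard scale per year; `b >= 0`.
#' @param c Senescent growth factor per year of age; `c >= 1`.
#' @param age_start,age_end First and terminal age of the table, in years.
#' @param sex Label attached to the table: `"male"`, `"female"` or
#'   `"combined"`.
#'
#' @return A tibble with columns `age`, `sex`, `q_annual` (one row per age,
#'   `q_annual[age_end] == 1`).
#' @examples
#' lt <- gm_life_table(a = 0.0005, b = 3.5e-5, c = 1.091, age_end = 110)
#' life_expectancy(lt, age = 36)
#' @export
gm_life_table <- function(a, b, c, age_start = 0, age_end = 110,
                          sex = c("combined", "male", "female")) {
  sex <- match.arg(sex)
  check_nonneg(a, "a"); check_nonneg(b, "b")
  if (!is.numeric(c) || is.na(c) || c < 1) {
    abort("`c` (senescent growth factor) must be >= 1.")
  }
  if (age_start >= age_end) abort("`age_start` must be below `age_end`.")
  age <- seq.int(age_start, age_end)
  q <- 1 - exp(-(a + b * c^age))
  q[length(q)] <- 1
  tibble(age = age, sex = sex, q_annual = q)
}

#' Packaged synthetic life tables
#'
#' Default mortality input for the cohort model: one Gompertz-Makeham table
#' per sex, with parameters frozen to give life expectancy at birth of about
#' 72 years (male) and 79 years (female), emulating the Brazilian 2014
#' sex-specific pattern. Terminal age 110.
#'
#' @param sex `"male"` or `"female"`.
#' @return A life-table tibble (`age`, `sex`, `q_annual`).
#' @export
synthetic_life_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  pars <- switch(sex,
    male   = list(a = 1.2e-3, b = 1.0e-4, c = 1.085),
    female = list(a = 5.0e-4, b = 5.0e-5, c = 1.090)
  )
  gm_life_table(pars$a, pars$b, pars$c, age_start = 0, age_end = 110,
                sex = sex)
}

validate_life_table <- function(table) {
  if (!is.data.frame(table) || !all(c("age", "q_annual") %in% names(table))) {
    abort("A life table needs columns `age` and `q_annual`.")
  }
  if (nrow(table) == 0) abort("Life table is empty.")
  if (any(diff(table$age) != 1)) abort("Life-table ages must be contiguous.")
  check_prob(table$q_annual, "q_annual")
  if (table$q_annual[nrow(table)] != 1) {
    abort("Terminal-age `q_annual` must equal 1.")
  }
  invisible(table)
}

#' Remaining life expectancy from an annual life table
#'
#' Computes expected remaining years at `age` by survival-product summation at
#' monthly resolution, with deaths placed on average halfway through the month
#' in which they occur (mid-period convention). Each annual probability is
#' first converted to a monthly one with [annual_to_monthly_prob()], so the
#' value is directly comparable with the monthly-cycle cohort engine.
#'
#' @param table A life-table tibble (`age`, `q_annual`).
#' @param age Age in whole years; must lie within the table range.
#' @return Expected remaining years (scalar).
#' @export
life_expectancy <- function(table, age) {
  validate_life_table(table)
  check_scalar(age, "age")
  if (age < table$age[1] || age > table$age[nrow(table)]) {
    abort(sprintf("`age` %s is outside the table range [%d, %d].",
                  format(age), table$age[1], table$age[nrow(table)]))
  }
  idx <- match(age, table$age)
  q_ann <- table$q_annual[idx:nrow(table)]
  p_month <- rep(1 - annual_to_monthly_prob(q_ann), each = 12L)
  surv <- cumprod(p_month)
  # mid-period: E = (sum_t S(t) + 1/2) months; survivors to the terminal age
  # die there (terminal q = 1), so S vanishes and the 1/2 applies in full
  (sum(surv) + 0.5) / 12
}

#' Convert an annual to a monthly probability
#'
#' Constant-hazard-within-year conversion: `p = 1 - (1 - q)^(1/12)`, so that
#' twelve repeated monthly applications compose back to the annual `q`.
#'
#' @param q Annual probability (vectorised), in \[0, 1\].
#' @return Monthly probability of the same event.
#' @export
annual_to_monthly_prob <- function(q) {
  check_prob(q, "q")
  1 - (1 - q)^(1 / 12)
}

#' Read and write life-table files
#'
#' Plain-text comma-separated files with header `age,sex,q_annual`.
#' Probabilities are written with 12 significant digits, enough for the
#' write/read cycle to reproduce the table bit-for-bit at that precision.
#'
#' @param table A life-table tibble.
#' @param path File path.
#' @return `read_life_table()` returns the tibble; `write_life_table()`
#'   returns `table` invisibly.
#' @export
write_life_table <- function(table, path) {
  validate_life_table(table)
  out <- data.frame(
    age = table$age,
    sex = if ("sex" %in% names(table)) table$sex else "combined",
    q_annual = formatC(table$q_annual, digits = 12, format = "g")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(),
    sex = readr::col_character(),
    q_annual = readr::col_double()
  ))
  validate_life_table(tbl)
  tbl
}
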