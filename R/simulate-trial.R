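#' Simulate per-patient UTI counts for one trial arm
#'
#' Draws each patient's lifetime-of-followup UTI count from a Poisson
#' distribution with mean `rate * months`, the count structure the evidence
#' pooling stage assumes when it converts arm-level incidence into a monthly
#' rate. Used as a self-contained test bed for the pooling stage; the
#' generator is fully reproducible under a fixed seed.
#'
#' @param rate Expected UTIs per patient-month; `rate >= 0`.
#' @param n_patients Number of patients in the arm.
#' @param months Follow-up duration in months.
#' @param seed Integer seed for the random generator.
#' @param arm_label Label stored in the `arm` column.
#' @return A tibble with columns `patient_id`, `arm`, `months`, `uti_count`
#'   and attributes `rate` and `seed`.
#' @examples
#' trial <- simulate_trial(rate = 0.48, n_patients = 114, months = 4, seed = 1)
#' estimate_rate(trial)
#' @export
simulate_trial <- function(rate, n_patients, months, seed,
                           arm_label = "pvc") {
  check_nonneg(rate, "rate"); check_scalar(rate, "rate")
  if (n_patients < 1) abort("`n_patients` must be >= 1.")
  if (months <= 0) abort("`months` must be > 0.")
  counts <- withr_seed(seed, rpois(n_patients, lambda = rate * months))
  out <- tibble(
    patient_id = seq_len(n_patients),
    arm = arm_label,
    months = months,
    uti_count = counts
  )
  attr(out, "rate") <- rate
  attr(out, "seed") <- seed
  out
}

## evaluate expr under a local L'Ecuyer stream, restoring the global state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Estimate the monthly event rate from simulated trial data
#'
#' Total events divided by total patient-months, the maximum-likelihood
#' estimate under the Poisson model [simulate_trial()] draws from.
#'
#' @param trial A tibble as returned by [simulate_trial()] (needs columns
#'   `months` and `uti_count`).
#' @return Estimated events per patient-month (scalar).
#' @export
estimate_rate <- function(trial) {
  if (!all(c("months", "uti_count") %in% names(trial))) {
    abort("`trial` needs columns `months` and `uti_count`.")
  }
  sum(trial$uti_count) / sum(trial$months)
}

#' @rdname simulate_trial
#' @param path File path for the delimited-text representation
#'   (`patient_id,arm,months,uti_count`).
#' @export
write_trial <- function(trial, path) {
  readr::write_csv(trial[, c("patient_id", "arm", "months", "uti_count")],
                   path)
  invisible(trial)
}

#' @rdname simulate_trial
#' @export
read_trial <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_integer(),
    arm = readr::col_character(),
    months = readr::col_double(),
    uti_count = readr::col_integer()
  ))
}
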