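## State space ------------------------------------------------------------

RENAL_LEVELS <- c("no_impairment", "significant_impairment", "renal_failure")
UTI_LEVELS <- c("no_uti", "first_line", "resistant_first", "resistant_second")

#' The model's health-state space
#'
#' Twelve alive states — three renal stages crossed with four UTI levels —
#' plus a single absorbing dead state. Renal function can only progress
#' (never recover); the UTI level is redrawn every cycle, independent of the
#' renal stage, so a UTI episode lasts exactly one monthly cycle.
#'
#' @return A tibble with columns `index`, `state`, `renal_stage`,
#'   `uti_level`, `alive`.
#' @export
health_states <- function() {
  grid <- expand.grid(uti_level = UTI_LEVELS, renal_stage = RENAL_LEVELS,
                      stringsAsFactors = FALSE)[, 2:1]
  tibble(
    index = seq_len(13),
    state = c(paste(grid$renal_stage, grid$uti_level, sep = "."), "dead"),
    renal_stage = c(grid$renal_stage, NA),
    uti_level = c(grid$uti_level, NA),
    alive = c(rep(TRUE, 12), FALSE)
  )
}

state_names <- function() health_states()$state

## index helpers over the 12 alive states (renal varies slowest)
renal_of <- function(s) (s - 1L) %/% 4L + 1L
uti_of <- function(s) (s - 1L) %% 4L + 1L

## Elementary operations ---------------------------------------------------

#' Split a monthly UTI probability across the antibiotic-resistance cascade
#'
#' A UTI episode (probability `p_uti`) responds to first-line antibiotics
#' with probability `1 - r1`; with probability `r1` it is first-line
#' resistant, and of those a fraction `r2` is also second-line resistant
#' (requiring parenteral third-line treatment). The four branch
#' probabilities sum to 1.
#'
#' @param p_uti Monthly probability of a UTI episode.
#' @param r1 First-line (ciprofloxacin) resistance probability.
#' @param r2 Second-line (cefuroxime) resistance probability, conditional on
#'   first-line resistance.
#' @return Named numeric vector `(no_uti, first_line, resistant_first,
#'   resistant_second)`.
#' @examples
#' uti_branch_probs(0.6248, 0.34, 0.034)
#' @export
uti_branch_probs <- function(p_uti, r1, r2) {
  check_prob(p_uti, "p_uti"); check_prob(r1, "r1"); check_prob(r2, "r2")
  setNames(
    c(1 - p_uti,
      p_uti * (1 - r1),
      p_uti * r1 * (1 - r2),
      p_uti * r1 * r2),
    UTI_LEVELS
  )
}

#' Apply a relative-risk treatment effect to a probability
#'
#' @param p_baseline Baseline (PVC) probability.
#' @param rr Relative risk under the intervention; `rr >= 0`.
#' @return `min(p_baseline * rr, 1)`.
#' @export
apply_treatment_effect <- function(p_baseline, rr) {
  check_prob(p_baseline, "p_baseline")
  check_nonneg(rr, "rr")
  pmin(p_baseline * rr, 1)
}

#' Scale a background death probability by an excess-hazard multiplier
#'
#' Applies a condition's mortality multiplier on the hazard scale: with
#' background monthly probability `q` and hazard `h = -log(1 - q)`, the
#' adjusted probability is `1 - exp(-h * (1 + m))`. A multiplier of 0 leaves
#' background mortality untouched; `q = 1` stays 1 for any multiplier.
#'
#' @param q_monthly_background Background monthly death probability.
#' @param multiplier Excess relative hazard `m >= 0` (vectorised).
#' @return Adjusted monthly death probability, in `[q, 1]`.
#' @export
adjusted_death_prob <- function(q_monthly_background, multiplier) {
  check_prob(q_monthly_background, "q_monthly_background")
  check_nonneg(multiplier, "multiplier")
  # q = 1 falls out naturally: log(0) = -Inf, exp(-Inf) = 0
  1 - exp(log(1 - q_monthly_background) * (1 + multiplier))
}

#' Resistance-weighted UTI mortality multiplier
#'
#' First-line-treatable UTIs carry no excess mortality and resistant UTIs
#' carry multiplier `m_resistant`, so the expected multiplier over an
#' arbitrary UTI episode is `m_resistant * r1` (e.g. 145.27 x 0.34 = 49.39).
#' Used for every active-UTI state when `uti_mortality_mode = "weighted"`.
#'
#' @param m_resistant Hazard multiplier of a resistant UTI.
#' @param r1 First-line resistance probability.
#' @return The weighted multiplier.
#' @export
weighted_uti_multiplier <- function(m_resistant, r1) {
  check_nonneg(m_resistant, "m_resistant")
  check_prob(r1, "r1")
  m_resistant * r1
}

## arm-specific monthly event probabilities
arm_event_probs <- function(params, arm) {
  arm <- match.arg(arm, c("pvc", "hydrophilic"))
  p_uti <- params$p_uti_pvc
  if (isTRUE(params$rate_to_prob)) p_uti <- 1 - exp(-p_uti)
  if (arm == "hydrophilic") p_uti <- apply_treatment_effect(p_uti, params$rr_uti)
  overlay <- c(
    bladder_stones = params$p_bladder_stones,
    kidney_stones = params$p_kidney_stones,
    urethral_injury = params$p_urethral_injury,
    urosepsis = params$p_urosepsis
  )
  if (arm == "hydrophilic") {
    overlay <- apply_treatment_effect(overlay, params$rr_other)
  }
  list(uti = p_uti, overlay = overlay)
}

## per-UTI-level excess multiplier according to the configured mode
uti_level_multipliers <- function(params) {
  if (params$uti_mortality_mode == "weighted") {
    m <- params$m_uti_weighted
    c(0, m, m, m)
  } else {
    c(0, params$m_uti_first, params$m_uti_resistant, params$m_uti_resistant)
  }
}

renal_level_multipliers <- function(params) {
  c(0, params$m_significant, params$m_renal_failure)
}

## per-alive-state monthly death probability
state_death_probs <- function(params, arm, q_monthly_background) {
  ev <- arm_event_probs(params, arm)
  m_uti <- uti_level_multipliers(params)
  m_renal <- renal_level_multipliers(params)
  m_sepsis <- ev$overlay[["urosepsis"]] * params$m_urosepsis
  s <- seq_len(12)
  m_total <- m_renal[renal_of(s)] + m_uti[uti_of(s)] + m_sepsis
  adjusted_death_prob(q_monthly_background, m_total)
}

#' Build the monthly transition matrix
#'
#' Constructs the 13 x 13 row-stochastic matrix for one cycle: from each
#' alive state, death occurs with the state's multiplier-adjusted background
#' probability ([adjusted_death_prob()]; urosepsis contributes its expected
#' per-cycle excess hazard to every alive state); survivors progress in renal
#' stage (no regression) and have their UTI level redrawn from
#' [uti_branch_probs()] independent of renal stage.
#'
#' @param params A [model_parameters()] object.
#' @param arm `"pvc"` or `"hydrophilic"`.
#' @param q_monthly_background Background monthly death probability for the
#'   cohort's current age.
#' @return A 13 x 13 matrix with `dimnames` the state names; rows sum to 1.
#' @export
build_transition_matrix <- function(params, arm, q_monthly_background) {
  stopifnot(inherits(params, "model_parameters"))
  check_prob(q_monthly_background, "q_monthly_background")
  check_scalar(q_monthly_background, "q_monthly_background")
  ev <- arm_event_probs(params, arm)
  u <- uti_branch_probs(ev$uti, params$r1, params$r2)
  rp <- matrix(c(1 - params$p_renal_progression, params$p_renal_progression, 0,
                 0, 1 - params$p_renal_failure, params$p_renal_failure,
                 0, 0, 1),
               nrow = 3, byrow = TRUE)
  q_d <- state_death_probs(params, arm, q_monthly_background)
  M <- matrix(0, 13, 13, dimnames = list(state_names(), state_names()))
  for (s in seq_len(12)) {
    r <- renal_of(s)
    for (s2 in seq_len(12)) {
      M[s, s2] <- (1 - q_d[s]) * rp[r, renal_of(s2)] * u[uti_of(s2)]
    }
    M[s, 13] <- q_d[s]
  }
  M[13, 13] <- 1
  M
}

## Cohort engine -----------------------------------------------------------

#' Run the Markov cohort model for one arm and sex
#'
#' Propagates a cohort entering at `params$entry_age` in the
#' (no impairment, no UTI) state through monthly cycles until the alive
#' fraction is extinguished (or `max_age` is reached). The background
#' monthly death probability is looked up from the annual life table for the
#' cohort's current integer age via [annual_to_monthly_prob()], and the
#' age-specific transition matrix is rebuilt each cycle.
#'
#' Alongside the state occupancy the engine records expected overlay-event
#' counts per cycle: the four non-UTI adverse events as (alive occupancy at
#' cycle start) x (arm-adjusted monthly probability), and UTI episodes as
#' the active-UTI occupancy the cycle transition produces.
#'
#' @param params A [model_parameters()] object.
#' @param arm `"pvc"` or `"hydrophilic"`.
#' @param life_table An annual life table (`age`, `q_annual`), e.g. from
#'   [synthetic_life_table()].
#' @param max_age Stop simulating when the cohort reaches this age; defaults
#'   to the table's terminal age (where `q = 1` ends the cohort anyway).
#' @return An object of class `cohort_trace`: occupancy matrix
#'   (cycles + 1 rows including cycle 0, 13 state columns), per-cycle event
#'   matrix (columns `uti`, `bladder_stones`, `kidney_stones`,
#'   `urethral_injury`, `urosepsis`), and run metadata. Convert with
#'   [as_tibble()]; plot with [autoplot()].
#' @examples
#' trace <- run_cohort(model_parameters(), "pvc", synthetic_life_table("male"))
#' trace
#' @export
run_cohort <- function(params, arm = c("pvc", "hydrophilic"), life_table,
                       max_age = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  arm <- match.arg(arm)
  validate_life_table(life_table)
  entry_age <- params$entry_age
  terminal_age <- life_table$age[nrow(life_table)]
  max_age <- max_age %||% terminal_age
  if (max_age > terminal_age) abort("`max_age` exceeds the table's terminal age.")
  if (entry_age < life_table$age[1] || entry_age >= terminal_age) {
    abort(sprintf("`entry_age` %d is outside the life table's range.",
                  entry_age))
  }
  n_cycles <- (max_age - entry_age) * 12L
  occ <- matrix(0, n_cycles + 1L, 13,
                dimnames = list(NULL, state_names()))
  occ[1, 1] <- 1 # everyone enters with no impairment, no UTI
  ev <- arm_event_probs(params, arm)
  events <- matrix(0, n_cycles, 5,
                   dimnames = list(NULL, c("uti", names(ev$overlay))))
  active_uti <- which(uti_of(seq_len(12)) >= 2L)
  last <- n_cycles
  q_month_cache <- NULL
  age_cached <- NA_integer_
  M <- NULL
  for (cyc in seq_len(n_cycles)) {
    age <- entry_age + (cyc - 1L) %/% 12L
    if (!identical(age, age_cached)) {
      q_ann <- life_table$q_annual[match(age, life_table$age)]
      M <- build_transition_matrix(params, arm, annual_to_monthly_prob(q_ann))
      age_cached <- age
    }
    v <- occ[cyc, ]
    alive_start <- sum(v[1:12])
    v_new <- as.numeric(v %*% M)
    occ[cyc + 1L, ] <- v_new
    events[cyc, "uti"] <- sum(v_new[active_uti])
    events[cyc, 2:5] <- alive_start * ev$overlay
    if (sum(v_new[1:12]) < 1e-9) { last <- cyc; break }
  }
  structure(
    list(
      occupancy = occ[seq_len(last + 1L), , drop = FALSE],
      events = events[seq_len(last), , drop = FALSE],
      cycles = last,
      arm = arm,
      sex = if ("sex" %in% names(life_table)) life_table$sex[1] else "combined",
      entry_age = entry_age,
      accrual = params$accrual,
      params = params
    ),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf(
    "Cohort trace: %s arm, %s, entry age %d, %d monthly cycles\n",
    x$arm, x$sex, x$entry_age, x$cycles))
  cat(sprintf("  expected lifetime UTI episodes: %.2f\n",
              sum(x$events[, "uti"])))
  cat(sprintf("  undiscounted life expectancy in model: %.2f years\n",
              undiscounted_ly(x)))
  invisible(x)
}

## undiscounted person-years in the trace under its accrual convention
undiscounted_ly <- function(trace) {
  alive <- rowSums(trace$occupancy[, 1:12, drop = FALSE])
  w <- accrual_weights(alive, trace$accrual)
  sum(w) / 12
}

## per-cycle accrued occupancy (vector or column), cycle c spans rows c, c+1
accrual_weights <- function(series, accrual) {
  n <- length(series)
  if (accrual == "midpoint") {
    (series[-n] + series[-1]) / 2
  } else {
    series[-n]
  }
}

#' @export
as_tibble.cohort_trace <- function(x, ...) {
  occ <- as_tibble(x$occupancy)
  occ$cycle <- seq_len(nrow(occ)) - 1L
  occ$age <- x$entry_age + occ$cycle / 12
  ev <- as_tibble(x$events)
  names(ev) <- paste0("events_", names(ev))
  pad <- ev[1, ]
  pad[1, ] <- NA_real_ # no events at cycle 0
  ev <- dplyr::bind_rows(pad, ev)
  dplyr::bind_cols(occ[, c("cycle", "age")],
                   occ[, state_names()], ev)
}

#' Plot a cohort trace
#'
#' Stacked occupancy over time, aggregated to renal stage (alive states) plus
#' death.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df, dplyr::all_of(state_names()),
                              names_to = "state", values_to = "occupancy")
  long$group <- ifelse(long$state == "dead", "dead",
                       sub("\\.[^.]+$", "", long$state))
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$age, .data$group),
    occupancy = sum(.data$occupancy), .groups = "drop")
  agg$group <- factor(agg$group, levels = c(RENAL_LEVELS, "dead"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                    fill = .data$group)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Cohort fraction", fill = NULL,
                  title = sprintf("Cohort occupancy, %s arm (%s)",
                                  object$arm, object$sex)) +
    ggplot2::theme_minimal()
}

#' Export a cohort trace to a delimited file
#'
#' One row per cycle with all 13 state occupancies and the 5 expected event
#' counts.
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path (CSV).
#' @return `trace`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path)
  invisible(trace)
}
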