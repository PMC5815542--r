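#' Discount factor for a monthly cycle
#'
#' Converts an annual discount rate to the factor applied at cycle index
#' `t` (months): `(1 + annual_rate)^(-t / 12)`. Fractional indices are
#' allowed (the midpoint accrual convention discounts at `t - 0.5`).
#'
#' @param annual_rate Annual discount rate, e.g. `0.05`.
#' @param cycle_index Cycle index in months (vectorised), `>= 0`.
#' @return Discount factor in `(0, 1]`.
#' @export
discount_factor <- function(annual_rate, cycle_index) {
  check_nonneg(annual_rate, "annual_rate")
  check_nonneg(cycle_index, "cycle_index")
  (1 + annual_rate)^(-cycle_index / 12)
}

## per-alive-state monthly cost (consumables + renal state care)
state_monthly_costs <- function(costs, arm) {
  consumable <- if (arm == "pvc") {
    costs$catheter_pvc + costs$lubricant_month * costs$tubes_per_day / 2
  } else {
    costs$catheter_hydro
  }
  renal <- c(0, costs$significant_month, costs$renal_failure_month)
  consumable + renal[renal_of(seq_len(12))]
}

## per-alive-state utility (baseline minus state decrements, floored at 0)
state_utilities <- function(utilities) {
  dec_renal <- c(0, utilities$significant, utilities$renal_failure)
  dec_uti <- c(0, utilities$uti, utilities$uti_resistant,
               utilities$uti_resistant)
  s <- seq_len(12)
  pmax(0, utilities$u0 - dec_renal[renal_of(s)] - dec_uti[uti_of(s)])
}

per_event_costs <- function(costs) {
  c(uti = costs$uti_event + costs$uti_antibiotics,
    bladder_stones = costs$bladder_stones,
    kidney_stones = costs$kidney_stones,
    urethral_injury = costs$urethral_injury,
    urosepsis = costs$urosepsis)
}

per_event_decrements <- function(utilities) {
  c(uti = 0, # UTI disutility is carried by the UTI states themselves
    bladder_stones = utilities$bladder_stones,
    kidney_stones = utilities$kidney_stones,
    urethral_injury = utilities$urethral_injury,
    urosepsis = utilities$urosepsis)
}

## accrued (convention-weighted) occupancy per cycle: rows = cycles,
## cols = 12 alive states
accrued_occupancy <- function(trace) {
  occ <- trace$occupancy[, 1:12, drop = FALSE]
  n <- nrow(occ)
  if (trace$accrual == "midpoint") {
    (occ[-n, , drop = FALSE] + occ[-1, , drop = FALSE]) / 2
  } else {
    occ[-n, , drop = FALSE]
  }
}

cycle_discounts <- function(trace, annual_rate) {
  idx <- seq_len(trace$cycles)
  t_eff <- if (trace$accrual == "midpoint") idx - 0.5 else idx - 1
  discount_factor(annual_rate, t_eff)
}

#' Per-cycle undiscounted costs of a cohort trace
#'
#' For each cycle: accrued alive occupancy times the arm's monthly
#' consumable cost, plus renal-state monthly care costs, plus expected event
#' counts times per-event costs (a UTI episode incurs the treatment cost and
#' one antibiotics course).
#'
#' @param trace A [run_cohort()] trace.
#' @param costs A [cost_schedule()].
#' @return Numeric vector, one undiscounted BRL amount per cycle.
#' @export
cycle_costs <- function(trace, costs) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costs, "cost_schedule"))
  occ <- accrued_occupancy(trace)
  state_part <- as.numeric(occ %*% state_monthly_costs(costs, trace$arm))
  event_part <- as.numeric(trace$events %*%
                             per_event_costs(costs)[colnames(trace$events)])
  state_part + event_part
}

#' Per-cycle undiscounted QALYs of a cohort trace
#'
#' Accrued occupancy times per-state utility (baseline minus state
#' decrements, floored at 0) over 12, minus expected overlay-event counts
#' times event decrements over 12; each cycle's total is floored at 0.
#'
#' @param trace A [run_cohort()] trace.
#' @param utilities A [utility_schedule()].
#' @return Numeric vector, one undiscounted QALY amount per cycle.
#' @export
cycle_qalys <- function(trace, utilities) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(utilities, "utility_schedule"))
  occ <- accrued_occupancy(trace)
  state_part <- as.numeric(occ %*% state_utilities(utilities)) / 12
  event_part <- as.numeric(trace$events %*%
                             per_event_decrements(utilities)[colnames(trace$events)]) / 12
  pmax(0, state_part - event_part)
}

#' Accumulate a cohort trace into arm-level economic outcomes
#'
#' Discounted lifetime cost, QALYs and life years, plus the undiscounted
#' expected lifetime UTI count (UTIs are never discounted). Discounting uses
#' [discount_factor()] at each cycle's accrual point.
#'
#' @param trace A [run_cohort()] trace.
#' @param costs A [cost_schedule()].
#' @param utilities A [utility_schedule()].
#' @param annual_rate Annual discount rate (default 5%).
#' @return An object of class `arm_outcomes`: a one-row tibble with columns
#'   `arm`, `sex`, `cost`, `qalys`, `lyg`, `uti_count`, with the per-cycle
#'   breakdown in attribute `"cycles"`.
#' @examples
#' tr <- run_cohort(model_parameters(), "pvc", synthetic_life_table("male"))
#' accumulate_outcomes(tr, cost_schedule(), utility_schedule())
#' @export
accumulate_outcomes <- function(trace, costs, utilities, annual_rate = 0.05) {
  df <- cycle_discounts(trace, annual_rate)
  cost_cycle <- cycle_costs(trace, costs)
  qaly_cycle <- cycle_qalys(trace, utilities)
  alive <- rowSums(trace$occupancy[, 1:12, drop = FALSE])
  ly_cycle <- accrual_weights(alive, trace$accrual) / 12
  breakdown <- tibble(
    cycle = seq_len(trace$cycles),
    discount = df,
    cost = cost_cycle,
    qalys = qaly_cycle,
    ly = ly_cycle,
    uti = trace$events[, "uti"]
  )
  out <- tibble(
    arm = trace$arm,
    sex = trace$sex,
    cost = sum(cost_cycle * df),
    qalys = sum(qaly_cycle * df),
    lyg = sum(ly_cycle * df),
    uti_count = sum(trace$events[, "uti"])
  )
  attr(out, "cycles") <- breakdown
  attr(out, "annual_rate") <- annual_rate
  class(out) <- c("arm_outcomes", class(out))
  out
}

#' Combine per-sex arm outcomes by cohort weights
#'
#' The model runs male and female cohorts separately against their own life
#' tables and mixes the outcomes at the end (default 80% male / 20% female),
#' rather than blending mortality within a single table.
#'
#' @param male,female `arm_outcomes` for the two sexes (same arm).
#' @param prop_male Male share of the cohort.
#' @return An `arm_outcomes` row with `sex = "combined"`.
#' @export
combine_sexes <- function(male, female, prop_male = 0.80) {
  check_prob(prop_male, "prop_male")
  stopifnot(male$arm == female$arm)
  w <- c(prop_male, 1 - prop_male)
  out <- tibble(
    arm = male$arm,
    sex = "combined",
    cost = w[1] * male$cost + w[2] * female$cost,
    qalys = w[1] * male$qalys + w[2] * female$qalys,
    lyg = w[1] * male$lyg + w[2] * female$lyg,
    uti_count = w[1] * male$uti_count + w[2] * female$uti_count
  )
  class(out) <- c("arm_outcomes", class(out))
  out
}
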