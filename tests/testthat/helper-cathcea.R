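# shared fixture builders (all data constructed in code)

# flat-hazard life table: q constant until the terminal age
flat_life_table <- function(q, age_start = 0, age_end = 110,
                            sex = "combined") {
  n <- age_end - age_start + 1
  tibble::tibble(
    age = seq.int(age_start, age_end),
    sex = sex,
    q_annual = c(rep(q, n - 1), 1)
  )
}

# parameters with every disease mechanism switched off
zero_disease_params <- function(...) {
  model_parameters(
    p_uti_pvc = 0, p_bladder_stones = 0, p_kidney_stones = 0,
    p_urethral_injury = 0, p_urosepsis = 0,
    p_renal_progression = 0, p_renal_failure = 0,
    m_uti_first = 0, m_uti_resistant = 0, m_uti_weighted = 0,
    m_urosepsis = 0, m_significant = 0, m_renal_failure = 0,
    ...
  )
}

# hand-built cohort trace for economics unit tests: `rows` is a matrix of
# occupancy over the 13 states (one row per cycle boundary), `events` one
# row per cycle over the 5 event types
make_trace <- function(rows, events = NULL, arm = "pvc",
                       accrual = "midpoint") {
  states <- health_states()$state
  colnames(rows) <- states
  n_cycles <- nrow(rows) - 1
  if (is.null(events)) {
    events <- matrix(0, n_cycles, 5)
  }
  colnames(events) <- c("uti", "bladder_stones", "kidney_stones",
                        "urethral_injury", "urosepsis")
  structure(
    list(occupancy = rows, events = events, cycles = n_cycles, arm = arm,
         sex = "combined", entry_age = 36, accrual = accrual,
         params = model_parameters(accrual = accrual)),
    class = "cohort_trace"
  )
}

# occupancy matrix fully alive in one state for n_cycles
constant_occupancy <- function(state_index, n_cycles) {
  rows <- matrix(0, n_cycles + 1, 13)
  rows[, state_index] <- 1
  rows
}

# arm_outcomes row built directly from numbers (for incremental arithmetic)
outcomes_row <- function(arm, cost, qalys, lyg, uti_count) {
  out <- tibble::tibble(arm = arm, sex = "combined", cost = cost,
                        qalys = qalys, lyg = lyg, uti_count = uti_count)
  class(out) <- c("arm_outcomes", class(out))
  out
}
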