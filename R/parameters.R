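#' Model parameters for the catheter Markov cohort model
#'
#' Bundles every epidemiological input driving the monthly transition
#' structure: the baseline (PVC) monthly adverse-event probabilities, the
#' hydrophilic treatment effects, the antibiotic-resistance cascade, renal
#' progression, mortality multipliers and the cohort definition. Defaults are
#' the model's base case: a spinal-cord-injury cohort entering at age 36,
#' 80% male, with a 62.48% monthly UTI probability under PVC catheters and a
#' pooled relative risk of 0.84 for hydrophilic catheters.
#'
#' @param p_uti_pvc Monthly UTI probability under PVC catheters. The base
#'   value is the patient-weighted pooled monthly rate from
#'   [pool_evidence()], used directly as a probability; set
#'   `rate_to_prob = TRUE` to pass it through `1 - exp(-rate)` instead.
#' @param rr_uti Treatment effect (relative risk, hydrophilic vs PVC) on UTI.
#' @param r1 Probability that a UTI is resistant to first-line antibiotics
#'   (ciprofloxacin).
#' @param r2 Probability that a first-line-resistant UTI is also resistant to
#'   the second line (cefuroxime); such episodes need parenteral third-line
#'   treatment.
#' @param p_bladder_stones,p_kidney_stones,p_urethral_injury,p_urosepsis
#'   Monthly probabilities of the overlay adverse events under PVC.
#' @param rr_other Treatment effect applied to all overlay events for the
#'   hydrophilic arm.
#' @param p_renal_progression Monthly probability of progressing from no
#'   renal impairment to significant impairment. Not published for this
#'   cohort; the default is an order-of-magnitude placeholder and every
#'   packaged acceptance quantity is independent of it.
#' @param p_renal_failure Monthly probability significant impairment ->
#'   renal failure (same caveat).
#' @param m_uti_first,m_uti_resistant Excess-mortality hazard multipliers for
#'   first-line-treatable and resistant UTI states. Applied on the hazard
#'   scale: background monthly hazard h becomes `h * (1 + m)`, so `m = 0`
#'   reproduces background mortality exactly.
#' @param m_uti_weighted Resistance-weighted UTI multiplier applied to every
#'   active-UTI state in `"weighted"` mode. It is a model input in its own
#'   right (the input table prints it as one); the default is
#'   [weighted_uti_multiplier()]`(145.27, 0.34)` = 49.39, and it is *not*
#'   recomputed when `r1` is varied in sensitivity analysis.
#' @param m_urosepsis Hazard multiplier for a urosepsis event; contributes
#'   `p_urosepsis * m_urosepsis` of excess hazard to every alive state (an
#'   expected-event overlay, since urosepsis is not a Markov state).
#' @param m_significant,m_renal_failure Hazard multipliers for the two
#'   impaired renal stages.
#' @param uti_mortality_mode `"weighted"` (default) applies the single
#'   resistance-weighted multiplier [weighted_uti_multiplier()] =
#'   `m_uti_resistant * r1` to all three active-UTI levels;
#'   `"state_specific"` applies `m_uti_first` to the first-line state and
#'   `m_uti_resistant` to the two resistant states.
#' @param prop_male Proportion of the cohort that is male.
#' @param entry_age Age in whole years at model entry.
#' @param rate_to_prob Convert `p_uti_pvc` from an event rate to a
#'   probability via `1 - exp(-rate)` (default `FALSE`: the pooled monthly
#'   value is used directly as a probability).
#' @param accrual Cycle accounting convention: `"midpoint"` (default; state
#'   occupancy accrues as the mean of adjacent cycle boundaries, deaths count
#'   half a cycle, matching the mid-period life-table convention) or
#'   `"start"` (spreadsheet-style start-of-cycle occupancy).
#'
#' @return A validated list of class `model_parameters`.
#' @examples
#' params <- model_parameters()
#' params$p_uti_pvc
#' @export
model_parameters <- function(p_uti_pvc = 0.6248,
                             rr_uti = 0.84,
                             r1 = 0.34,
                             r2 = 0.034,
                             p_bladder_stones = 0.0012,
                             p_kidney_stones = 0.0012,
                             p_urethral_injury = 0.0019,
                             p_urosepsis = 0.0032,
                             rr_other = 0.90,
                             p_renal_progression = 0.0004,
                             p_renal_failure = 0.0029,
                             m_uti_first = 0,
                             m_uti_resistant = 145.27,
                             m_uti_weighted = weighted_uti_multiplier(145.27, 0.34),
                             m_urosepsis = 797.6,
                             m_significant = 18,
                             m_renal_failure = 54,
                             uti_mortality_mode = c("weighted",
                                                    "state_specific"),
                             prop_male = 0.80,
                             entry_age = 36,
                             rate_to_prob = FALSE,
                             accrual = c("midpoint", "start")) {
  uti_mortality_mode <- match.arg(uti_mortality_mode)
  accrual <- match.arg(accrual)
  for (nm in c("p_uti_pvc", "r1", "r2", "p_bladder_stones", "p_kidney_stones",
               "p_urethral_injury", "p_urosepsis", "p_renal_progression",
               "p_renal_failure", "prop_male")) {
    check_prob(get(nm), nm); check_scalar(get(nm), nm)
  }
  for (nm in c("rr_uti", "rr_other", "m_uti_first", "m_uti_resistant",
               "m_uti_weighted", "m_urosepsis", "m_significant",
               "m_renal_failure")) {
    check_nonneg(get(nm), nm); check_scalar(get(nm), nm)
  }
  if (entry_age < 0) abort("`entry_age` must be >= 0.")
  structure(
    list(
      p_uti_pvc = p_uti_pvc, rr_uti = rr_uti, r1 = r1, r2 = r2,
      p_bladder_stones = p_bladder_stones,
      p_kidney_stones = p_kidney_stones,
      p_urethral_injury = p_urethral_injury,
      p_urosepsis = p_urosepsis,
      rr_other = rr_other,
      p_renal_progression = p_renal_progression,
      p_renal_failure = p_renal_failure,
      m_uti_first = m_uti_first, m_uti_resistant = m_uti_resistant,
      m_uti_weighted = m_uti_weighted,
      m_urosepsis = m_urosepsis, m_significant = m_significant,
      m_renal_failure = m_renal_failure,
      uti_mortality_mode = uti_mortality_mode,
      prop_male = prop_male, entry_age = entry_age,
      rate_to_prob = rate_to_prob, accrual = accrual
    ),
    class = "model_parameters"
  )
}

#' Restrict the model to UTI as the only adverse event
#'
#' Preset for the secondary analysis: zeroes the overlay adverse events
#' (bladder and kidney stones, urethral injury, urosepsis) so UTIs are the
#' single complication, leaving everything else at the supplied values.
#'
#' @param params A [model_parameters()] object.
#' @return A `model_parameters` object with overlay probabilities set to 0.
#' @export
uti_only_parameters <- function(params = model_parameters()) {
  stopifnot(inherits(params, "model_parameters"))
  params$p_bladder_stones <- 0
  params$p_kidney_stones <- 0
  params$p_urethral_injury <- 0
  params$p_urosepsis <- 0
  params
}

#' Cost schedule (2016 BRL)
#'
#' Unit costs from the public-payer perspective: monthly consumables per arm,
#' per-event treatment costs and per-state monthly costs for impaired renal
#' function. The PVC arm additionally pays for lubricant; the base case
#' assumes four catheterisations per day using half a tube each, i.e. 2
#' tubes/day, and the lubricant cost scales linearly in `tubes_per_day`.
#'
#' @param catheter_pvc,catheter_hydro Monthly catheter cost per arm, BRL.
#' @param lubricant_month Monthly lubricant cost at the reference 2
#'   tubes/day, BRL (PVC arm only).
#' @param tubes_per_day Lubricant tubes used per day (reference 2).
#' @param uti_event Cost per treated UTI episode, BRL.
#' @param uti_antibiotics Antibiotic cost applied once per UTI episode
#'   regardless of line, BRL.
#' @param urosepsis,urethral_injury,kidney_stones,bladder_stones Per-event
#'   costs, BRL.
#' @param significant_month,renal_failure_month Monthly cost of the impaired
#'   renal states, BRL.
#' @return A validated list of class `cost_schedule`.
#' @export
cost_schedule <- function(catheter_pvc = 74.27,
                          catheter_hydro = 608.27,
                          lubricant_month = 132.75,
                          tubes_per_day = 2,
                          uti_event = 554.16,
                          uti_antibiotics = 60.50,
                          urosepsis = 708.36,
                          urethral_injury = 605.33,
                          kidney_stones = 524.30,
                          bladder_stones = 721.95,
                          significant_month = 82.60,
                          renal_failure_month = 2589.02) {
  vals <- list(
    catheter_pvc = catheter_pvc, catheter_hydro = catheter_hydro,
    lubricant_month = lubricant_month, tubes_per_day = tubes_per_day,
    uti_event = uti_event, uti_antibiotics = uti_antibiotics,
    urosepsis = urosepsis, urethral_injury = urethral_injury,
    kidney_stones = kidney_stones, bladder_stones = bladder_stones,
    significant_month = significant_month,
    renal_failure_month = renal_failure_month
  )
  for (nm in names(vals)) { check_nonneg(vals[[nm]], nm); check_scalar(vals[[nm]], nm) }
  structure(vals, class = "cost_schedule")
}

#' Utility schedule
#'
#' Baseline utility of the cohort and the decrements applied while a state or
#' event is active. The baseline `u0` for this cohort was never published;
#' the default 0.50 is a package assumption (flagged as such in the config
#' schema), and the packaged acceptance quantities avoid it. State decrements
#' (UTI levels, renal stages) apply for each cycle spent in the state; event
#' decrements (stones, urethral injury, urosepsis) apply for one cycle per
#' expected event. Per-state utility is floored at 0.
#'
#' @param u0 Baseline utility in \[0, 1\] (assumption, see Details).
#' @param uti,uti_resistant Decrements for first-line-treatable and
#'   antibiotic-resistant UTI cycles.
#' @param kidney_stones,bladder_stones,urethral_injury,urosepsis Per-event
#'   decrements.
#' @param significant,renal_failure Decrements for the impaired renal stages.
#' @return A validated list of class `utility_schedule`.
#' @export
utility_schedule <- function(u0 = 0.50,
                             uti = 0.060,
                             uti_resistant = 0.104,
                             kidney_stones = 0.050,
                             bladder_stones = 0.050,
                             urethral_injury = 0.104,
                             urosepsis = 0.160,
                             significant = 0.155,
                             renal_failure = 0.250) {
  check_prob(u0, "u0")
  vals <- list(
    u0 = u0, uti = uti, uti_resistant = uti_resistant,
    kidney_stones = kidney_stones, bladder_stones = bladder_stones,
    urethral_injury = urethral_injury, urosepsis = urosepsis,
    significant = significant, renal_failure = renal_failure
  )
  for (nm in names(vals)) { check_nonneg(vals[[nm]], nm); check_scalar(vals[[nm]], nm) }
  structure(vals, class = "utility_schedule")
}
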