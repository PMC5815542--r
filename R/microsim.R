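#' Per-patient microsimulation of the catheter model
#'
#' Independent stochastic counterpart of [run_cohort()]: each patient's
#' monthly path is sampled individually under exactly the same transition
#' rules, event probabilities and accrual conventions, and economic outcomes
#' are accumulated per patient. Because the cohort trace is the expectation
#' of this process, sample means converge to the cohort results as
#' `n_patients` grows; the function is used to cross-validate the
#' deterministic engine.
#'
#' @param params A [model_parameters()] object.
#' @param arm `"pvc"` or `"hydrophilic"`.
#' @param life_table Annual life table for one sex.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed (results are reproducible given the seed).
#' @param costs A [cost_schedule()].
#' @param utilities A [utility_schedule()].
#' @param annual_rate Annual discount rate.
#' @param max_age Optional stopping age (defaults to the table's terminal
#'   age).
#' @return An object of class `microsim_result`: a one-row tibble with mean
#'   discounted `cost`, `qalys`, `lyg` and undiscounted `uti_count` per
#'   patient plus their Monte-Carlo standard errors (`*_se`); the per-patient
#'   outcome matrix is kept in attribute `"patients"`.
#' @examples
#' ms <- run_microsim(model_parameters(), "pvc", synthetic_life_table("male"),
#'                    n_patients = 500, seed = 1)
#' ms
#' @export
run_microsim <- function(params, arm = c("pvc", "hydrophilic"), life_table,
                         n_patients, seed,
                         costs = cost_schedule(),
                         utilities = utility_schedule(),
                         annual_rate = 0.05, max_age = NULL) {
  stopifnot(inherits(params, "model_parameters"))
  arm <- match.arg(arm)
  validate_life_table(life_table)
  if (n_patients < 1) abort("`n_patients` must be >= 1.")
  entry_age <- params$entry_age
  terminal_age <- life_table$age[nrow(life_table)]
  max_age <- max_age %||% terminal_age
  n_cycles <- (max_age - entry_age) * 12L

  ev <- arm_event_probs(params, arm)
  u_branch <- uti_branch_probs(ev$uti, params$r1, params$r2)
  u_cum <- cumsum(u_branch)
  s_cost <- state_monthly_costs(costs, arm)
  s_util <- state_utilities(utilities)
  e_cost <- per_event_costs(costs)
  e_dec <- per_event_decrements(utilities)
  overlay_names <- names(ev$overlay)
  midpoint <- params$accrual == "midpoint"

  acc <- matrix(0, n_patients, 4,
                dimnames = list(NULL, c("cost", "qalys", "lyg", "uti_count")))

  withr_seed(seed, {
    renal <- rep(1L, n_patients)
    uti <- rep(1L, n_patients)
    alive <- rep(TRUE, n_patients)
    for (cyc in seq_len(n_cycles)) {
      idx <- which(alive)
      if (!length(idx)) break
      age <- entry_age + (cyc - 1L) %/% 12L
      q_month <- annual_to_monthly_prob(
        life_table$q_annual[match(age, life_table$age)])
      q_d <- state_death_probs(params, arm, q_month)
      t_eff <- if (midpoint) cyc - 0.5 else cyc - 1
      df <- discount_factor(annual_rate, t_eff)
      n_a <- length(idx)
      s_prev <- (renal[idx] - 1L) * 4L + uti[idx]

      # overlay adverse events: everyone alive at cycle start is at risk
      ev_draw <- matrix(runif(n_a * 4) < rep(ev$overlay, each = n_a),
                        n_a, 4, dimnames = list(NULL, overlay_names))
      ev_cost <- as.numeric(ev_draw %*% e_cost[overlay_names])
      ev_dec <- as.numeric(ev_draw %*% e_dec[overlay_names])

      dies <- runif(n_a) < q_d[s_prev]
      surv <- !dies

      renal_new <- renal[idx]
      p_prog <- ifelse(renal_new == 1L, params$p_renal_progression,
                       ifelse(renal_new == 2L, params$p_renal_failure, 0))
      advance <- surv & (runif(n_a) < p_prog)
      renal_new[advance] <- renal_new[advance] + 1L

      uti_new <- rep(1L, n_a)
      uti_new[surv] <- findInterval(runif(sum(surv)), u_cum,
                                    left.open = TRUE) + 1L
      new_uti_episode <- surv & (uti_new >= 2L)
      s_new <- (renal_new - 1L) * 4L + uti_new

      cost_prev <- s_cost[s_prev]
      cost_new <- ifelse(surv, s_cost[s_new], 0)
      util_prev <- s_util[s_prev]
      util_new <- ifelse(surv, s_util[s_new], 0)
      if (midpoint) {
        state_cost <- (cost_prev + cost_new) / 2
        state_util <- (util_prev + util_new) / 2
        ly <- (1 + surv) / 2 / 12
      } else {
        state_cost <- cost_prev
        state_util <- util_prev
        ly <- rep(1 / 12, n_a)
      }
      cyc_cost <- state_cost + ev_cost + new_uti_episode * e_cost[["uti"]]
      cyc_qaly <- state_util / 12 - ev_dec / 12

      acc[idx, "cost"] <- acc[idx, "cost"] + cyc_cost * df
      acc[idx, "qalys"] <- acc[idx, "qalys"] + cyc_qaly * df
      acc[idx, "lyg"] <- acc[idx, "lyg"] + ly * df
      acc[idx, "uti_count"] <- acc[idx, "uti_count"] + new_uti_episode

      alive[idx] <- surv
      renal[idx] <- renal_new
      uti[idx] <- uti_new
    }
  })

  means <- colMeans(acc)
  ses <- apply(acc, 2, stats::sd) / sqrt(n_patients)
  out <- tibble(
    arm = arm,
    sex = if ("sex" %in% names(life_table)) life_table$sex[1] else "combined",
    n_patients = n_patients, seed = seed,
    cost = means[["cost"]], cost_se = ses[["cost"]],
    qalys = means[["qalys"]], qalys_se = ses[["qalys"]],
    lyg = means[["lyg"]], lyg_se = ses[["lyg"]],
    uti_count = means[["uti_count"]], uti_count_se = ses[["uti_count"]]
  )
  attr(out, "patients") <- acc
  class(out) <- c("microsim_result", class(out))
  out
}
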