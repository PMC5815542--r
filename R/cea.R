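#' Incremental cost-effectiveness analysis between two arms
#'
#' Computes deltas (new minus comparator) and the three incremental
#' cost-effectiveness ratios: BRL per QALY gained, BRL per life year gained,
#' and BRL per UTI avoided (defined when the new arm has fewer UTIs). Each
#' ICER is computed from full-precision deltas and reported only when the
#' corresponding effect delta points the right way; dominance is classified
#' as `"dominant"` (no more costly, at least as effective, not identical),
#' `"dominated"` (at least as costly, no more effective) or `"interior"`.
#'
#' @param new_arm,comparator `arm_outcomes` rows (see
#'   [accumulate_outcomes()]); typically hydrophilic vs PVC.
#' @param threshold Willingness-to-pay ceiling in BRL per QALY (default
#'   147,000, the Brazilian estimate used for classification).
#' @return An object of class `incremental_result`: a list with the deltas,
#'   ICERs (`NA` where undefined), `dominance` and `cost_effective`.
#'   [tidy()] returns a delta/ICER table; [glance()] a one-row summary.
#' @examples
#' res <- run_cea()
#' glance(res$incremental)
#' @export
incremental <- function(new_arm, comparator, threshold = 147000) {
  check_nonneg(threshold, "threshold")
  d_cost <- new_arm$cost - comparator$cost
  d_qaly <- new_arm$qalys - comparator$qalys
  d_lyg <- new_arm$lyg - comparator$lyg
  d_uti <- new_arm$uti_count - comparator$uti_count
  icer_qaly <- if (d_qaly > 0) d_cost / d_qaly else NA_real_
  icer_lyg <- if (d_lyg > 0) d_cost / d_lyg else NA_real_
  cost_per_uti <- if (d_uti < 0) d_cost / (-d_uti) else NA_real_
  all_zero <- d_cost == 0 && d_qaly == 0
  dominance <- if (all_zero) {
    "interior"
  } else if (d_cost <= 0 && d_qaly >= 0) {
    "dominant"
  } else if (d_cost >= 0 && d_qaly <= 0) {
    "dominated"
  } else {
    "interior"
  }
  if (dominance == "dominant" && d_qaly > 0) icer_qaly <- d_cost / d_qaly
  cost_effective <- (dominance == "dominant") ||
    (dominance == "interior" && !is.na(icer_qaly) && icer_qaly <= threshold)
  structure(
    list(
      new_arm = new_arm$arm, comparator = comparator$arm,
      delta_cost = d_cost, delta_qaly = d_qaly, delta_lyg = d_lyg,
      delta_uti = d_uti,
      icer_per_qaly = icer_qaly, icer_per_lyg = icer_lyg,
      cost_per_uti_avoided = cost_per_uti,
      dominance = dominance, threshold = threshold,
      cost_effective = cost_effective
    ),
    class = "incremental_result"
  )
}

#' @export
tidy.incremental_result <- function(x, ...) {
  tibble(
    quantity = c("delta_cost", "delta_qaly", "delta_lyg", "delta_uti",
                 "icer_per_qaly", "icer_per_lyg", "cost_per_uti_avoided"),
    value = c(x$delta_cost, x$delta_qaly, x$delta_lyg, x$delta_uti,
              x$icer_per_qaly, x$icer_per_lyg, x$cost_per_uti_avoided),
    unit = c("BRL", "QALY", "years", "UTIs",
             "BRL/QALY", "BRL/LYG", "BRL/UTI")
  )
}

#' @export
glance.incremental_result <- function(x, ...) {
  tibble(
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    delta_lyg = x$delta_lyg, delta_uti = x$delta_uti,
    icer_per_qaly = x$icer_per_qaly, icer_per_lyg = x$icer_per_lyg,
    cost_per_uti_avoided = x$cost_per_uti_avoided,
    dominance = x$dominance, threshold = x$threshold,
    cost_effective = x$cost_effective
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental analysis: %s vs %s\n", x$new_arm, x$comparator))
  cat(sprintf("  Δcost %0.0f BRL | ΔQALY %.3f | ΔLYG %.3f | ΔUTI %.2f\n",
              x$delta_cost, x$delta_qaly, x$delta_lyg, x$delta_uti))
  fmt <- function(v, unit) {
    if (is.na(v)) sprintf("undefined (%s)", x$dominance)
    else sprintf("%0.0f %s", v, unit)
  }
  cat("  ICER:", fmt(x$icer_per_qaly, "BRL/QALY gained"), "\n")
  cat("  ICER:", fmt(x$icer_per_lyg, "BRL/LYG"), "\n")
  cat("  ICER:", fmt(x$cost_per_uti_avoided, "BRL/UTI avoided"), "\n")
  cat(sprintf("  %scost-effective at threshold %0.0f BRL/QALY\n",
              if (x$cost_effective) "" else "NOT ", x$threshold))
  invisible(x)
}

#' Run the full cost-effectiveness pipeline
#'
#' Simulates both catheter arms, each as separate male and female cohorts
#' against their life tables combined by the cohort's sex mix, accumulates
#' discounted costs, QALYs and life years (UTIs undiscounted), and performs
#' the incremental analysis of hydrophilic-coated versus uncoated PVC
#' catheters.
#'
#' @param params A [model_parameters()] object.
#' @param costs A [cost_schedule()].
#' @param utilities A [utility_schedule()].
#' @param life_tables Named list with elements `male` and `female`; defaults
#'   to the packaged synthetic tables.
#' @param analysis `"primary"` (all adverse events) or `"secondary"`
#'   (UTI as the only adverse event; applies [uti_only_parameters()]).
#' @param annual_rate Annual discount rate (default 5%).
#' @param threshold Willingness-to-pay threshold, BRL/QALY.
#' @return An object of class `cea_result`: per-arm outcomes (combined and
#'   per sex), the `incremental_result`, and the inputs used. [tidy()]
#'   returns the arm-outcome table; [glance()] the incremental summary.
#' @examples
#' res <- run_cea()
#' res
#' @export
run_cea <- function(params = model_parameters(),
                    costs = cost_schedule(),
                    utilities = utility_schedule(),
                    life_tables = list(male = synthetic_life_table("male"),
                                       female = synthetic_life_table("female")),
                    analysis = c("primary", "secondary"),
                    annual_rate = 0.05,
                    threshold = 147000) {
  analysis <- match.arg(analysis)
  if (analysis == "secondary") params <- uti_only_parameters(params)
  stopifnot(all(c("male", "female") %in% names(life_tables)))
  arm_results <- purrr::map(c(pvc = "pvc", hydrophilic = "hydrophilic"),
    function(arm) {
      per_sex <- purrr::map(life_tables[c("male", "female")], function(lt) {
        accumulate_outcomes(run_cohort(params, arm, lt), costs, utilities,
                            annual_rate)
      })
      combined <- combine_sexes(per_sex$male, per_sex$female,
                                params$prop_male)
      list(combined = combined, per_sex = per_sex)
    })
  inc <- incremental(arm_results$hydrophilic$combined,
                     arm_results$pvc$combined, threshold)
  structure(
    list(
      arms = dplyr::bind_rows(arm_results$pvc$combined,
                              arm_results$hydrophilic$combined),
      per_sex = dplyr::bind_rows(
        arm_results$pvc$per_sex$male, arm_results$pvc$per_sex$female,
        arm_results$hydrophilic$per_sex$male,
        arm_results$hydrophilic$per_sex$female),
      incremental = inc,
      analysis = analysis,
      params = params, costs = costs, utilities = utilities,
      annual_rate = annual_rate, threshold = threshold
    ),
    class = "cea_result"
  )
}

#' @export
tidy.cea_result <- function(x, ...) x$arms

#' @export
glance.cea_result <- function(x, ...) {
  dplyr::bind_cols(tibble(analysis = x$analysis),
                   glance(x$incremental))
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness results (%s analysis, %d%% discount)\n",
              x$analysis, round(100 * x$annual_rate)))
  df <- as.data.frame(x$arms)
  df$cost <- round(df$cost)
  df$qalys <- round(df$qalys, 3)
  df$lyg <- round(df$lyg, 3)
  df$uti_count <- round(df$uti_count, 2)
  names(df) <- c("arm", "sex", "Cost (BRL)", "QALYs", "LYG", "UTI")
  print(df[, -2], row.names = FALSE)
  print(x$incremental)
  invisible(x)
}

#' Compare discounted costs and effects across arms graphically
#'
#' Bar chart of per-arm discounted cost, QALYs, LYG and undiscounted UTI
#' count.
#'
#' @param object A `cea_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$arms,
                              c("cost", "qalys", "lyg", "uti_count"),
                              names_to = "outcome", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value,
                                     fill = .data$arm)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Arm outcomes (%s analysis)",
                                  object$analysis)) +
    ggplot2::theme_minimal()
}
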