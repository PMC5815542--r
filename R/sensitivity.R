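#' Default one-way sensitivity scenarios
#'
#' The three parameter groups examined one at a time around the base case:
#' lubricant tubes per day (base 2; single-use practice implies 4, a frugal
#' assumption 1), the first-line antibiotic resistance level (base 34%; a
#' conservative published 16.5% and a pessimistic 45%), and the UTI
#' reduction of hydrophilic catheters (base 16%, i.e. relative risk 0.84;
#' literature alternatives 26% and 53%, relative risks 0.74 and 0.47).
#'
#' @return A tibble with columns `scenario`, `parameter`, `value`, `label`.
#' @export
dsa_scenarios <- function() {
  tibble(
    scenario = c("tubes_per_day: 1", "tubes_per_day: 4",
                 "resistance: 16%", "resistance: 45%",
                 "uti_reduction: 26%", "uti_reduction: 53%"),
    parameter = c("tubes_per_day", "tubes_per_day", "r1", "r1",
                  "rr_uti", "rr_uti"),
    value = c(1, 4, 0.165, 0.45, 0.74, 0.47),
    label = c("assumed frugal use", "single-use guideline",
              "conservative published rate", "pessimistic assumption",
              "literature review", "long-term community data")
  )
}

apply_override <- function(params, costs, utilities, parameter, value) {
  if (parameter %in% names(unclass(params))) {
    args <- unclass(params)
    args[[parameter]] <- value
    params <- do.call(model_parameters, args)
  } else if (parameter %in% names(unclass(costs))) {
    args <- unclass(costs)
    args[[parameter]] <- value
    costs <- do.call(cost_schedule, args)
  } else if (parameter %in% names(unclass(utilities))) {
    args <- unclass(utilities)
    args[[parameter]] <- value
    utilities <- do.call(utility_schedule, args)
  } else {
    abort(sprintf("Unknown sensitivity parameter `%s`.", parameter))
  }
  list(params = params, costs = costs, utilities = utilities)
}

#' Deterministic one-way sensitivity analysis
#'
#' Re-runs the full pipeline once per scenario, each time overriding exactly
#' one parameter of the base configuration, and collects the resulting
#' ICERs. Varying `r1` shifts the composition of UTI episodes across the
#' antibiotic cascade (and hence the utility decrement mix); the weighted
#' UTI mortality multiplier is a separate model input and is deliberately
#' not recomputed, matching the one-at-a-time discipline of the analysis.
#'
#' @param scenarios A tibble like [dsa_scenarios()] (`scenario`, `parameter`,
#'   `value` columns; one row, hence one changed parameter, per scenario).
#' @param params,costs,utilities,life_tables,analysis,annual_rate,threshold
#'   Base configuration, as in [run_cea()].
#' @return An object of class `dsa_result`: a tibble with one row per
#'   scenario plus the base case (`scenario == "base"`), columns `parameter`,
#'   `value`, `icer_per_qaly`, `delta_cost`, `delta_qaly` and
#'   `icer_change` (difference from the base ICER).
#' @examples
#' \donttest{
#' dsa <- run_one_way(dsa_scenarios())
#' autoplot(dsa)
#' }
#' @export
run_one_way <- function(scenarios = dsa_scenarios(),
                        params = model_parameters(),
                        costs = cost_schedule(),
                        utilities = utility_schedule(),
                        life_tables = list(male = synthetic_life_table("male"),
                                           female = synthetic_life_table("female")),
                        analysis = c("primary", "secondary"),
                        annual_rate = 0.05,
                        threshold = 147000) {
  analysis <- match.arg(analysis)
  if (!all(c("scenario", "parameter", "value") %in% names(scenarios))) {
    abort("`scenarios` needs columns `scenario`, `parameter`, `value`.")
  }
  dup <- unique(scenarios$scenario[duplicated(scenarios$scenario)])
  if (length(dup)) {
    abort(paste0("One-way analysis: each scenario must change exactly one ",
                 "parameter; duplicated scenario name(s): ",
                 paste(dup, collapse = ", ")))
  }
  run_once <- function(p, co, ut) {
    glance(run_cea(p, co, ut, life_tables, analysis, annual_rate,
                   threshold)$incremental)
  }
  base <- run_once(params, costs, utilities)
  rows <- purrr::pmap(scenarios[, c("scenario", "parameter", "value")],
    function(scenario, parameter, value) {
      cfg <- apply_override(params, costs, utilities, parameter, value)
      res <- run_once(cfg$params, cfg$costs, cfg$utilities)
      dplyr::bind_cols(tibble(scenario = scenario, parameter = parameter,
                              value = value), res)
    })
  out <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(scenario = "base", parameter = NA_character_,
                            value = NA_real_), base),
    dplyr::bind_rows(rows)
  )
  out$icer_change <- out$icer_per_qaly - base$icer_per_qaly
  class(out) <- c("dsa_result", class(out))
  out
}

#' Order sensitivity scenarios by influence on the ICER
#'
#' Sorts the non-base scenarios by decreasing absolute deviation of their
#' ICER from the base-case ICER (the tornado-diagram ordering); ties are
#' broken alphabetically by scenario name.
#'
#' @param results A [run_one_way()] result.
#' @return The non-base rows of `results`, reordered.
#' @export
tornado_order <- function(results) {
  if (!is.data.frame(results) ||
      !all(c("scenario", "icer_per_qaly", "icer_change") %in% names(results))) {
    abort("`results` must be a `dsa_result` table.")
  }
  rows <- results[results$scenario != "base", , drop = FALSE]
  if (nrow(rows) == 0) abort("No non-base scenarios to order.")
  rows[order(-abs(rows$icer_change), rows$scenario), , drop = FALSE]
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars from the base-case ICER to each scenario's ICER, ordered
#' by influence.
#'
#' @param object A `dsa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsa_result <- function(object, ...) {
  base_icer <- object$icer_per_qaly[object$scenario == "base"]
  rows <- tornado_order(object)
  rows$scenario <- factor(rows$scenario, levels = rev(rows$scenario))
  ggplot2::ggplot(rows,
                  ggplot2::aes(y = .data$scenario,
                               xmin = pmin(.data$icer_per_qaly, base_icer),
                               xmax = pmax(.data$icer_per_qaly, base_icer))) +
    ggplot2::geom_linerange(linewidth = 6, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (BRL per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}
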