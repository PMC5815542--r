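#' Configuration schema
#'
#' One row per configurable field with its default and provenance:
#' `"published"` for values taken from the model's declared input tables and
#' `"assumption"` for package choices that have no published source (renal
#' progression probabilities, baseline utility, the synthetic life tables,
#' accounting conventions).
#'
#' @return A tibble with columns `section`, `field`, `default`, `provenance`.
#' @export
config_schema <- function() {
  p <- unclass(model_parameters())
  co <- unclass(cost_schedule())
  ut <- unclass(utility_schedule())
  run <- default_run_settings()
  assumption <- c("p_renal_progression", "p_renal_failure", "u0",
                  "uti_mortality_mode", "rate_to_prob", "accrual",
                  "life_tables", "seed", "tubes_per_day")
  mk <- function(section, lst) {
    tibble(section = section, field = names(lst),
           default = vapply(lst, function(v) paste(format(v), collapse = ","),
                            character(1)),
           provenance = ifelse(names(lst) %in% assumption, "assumption",
                               "published"))
  }
  dplyr::bind_rows(mk("parameters", p), mk("costs", co),
                   mk("utilities", ut), mk("run", run))
}

default_run_settings <- function() {
  list(analysis = "primary", annual_rate = 0.05, threshold = 147000,
       life_tables = "synthetic", seed = 1L)
}

#' Build, load and write run configurations
#'
#' A run configuration bundles the model parameters, cost and utility
#' schedules and run settings (analysis mode, discount rate, threshold,
#' life-table source, seed) into one validated object, serialisable to YAML.
#' `load_config()` requires every field of every section to be present and
#' rejects unknown keys, so a config file is always a complete, explicit
#' record of a run. The packaged base-case file is at
#' `system.file("extdata", "base_config.yaml", package = "cathcea")`.
#'
#' @param parameters,costs,utilities,run The four sections (defaults are
#'   the base case).
#' @return A list of class `run_config`.
#' @examples
#' cfg <- default_config()
#' cfg$parameters$p_uti_pvc
#' @export
default_config <- function(parameters = model_parameters(),
                           costs = cost_schedule(),
                           utilities = utility_schedule(),
                           run = default_run_settings()) {
  structure(list(parameters = parameters, costs = costs,
                 utilities = utilities, run = run),
            class = "run_config")
}

check_section <- function(got, want, section) {
  unknown <- setdiff(names(got), want)
  if (length(unknown)) {
    abort(sprintf("Unknown key(s) in `%s`: %s", section,
                  paste(paste0(section, ".", unknown), collapse = ", ")))
  }
  missing <- setdiff(want, names(got))
  if (length(missing)) {
    abort(sprintf("Missing required field(s) in `%s`: %s", section,
                  paste(paste0(section, ".", missing), collapse = ", ")))
  }
  got[want]
}

#' @rdname default_config
#' @param x A plain nested list (e.g. parsed YAML) to validate into a
#'   `run_config`.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  secs <- check_section(x, c("parameters", "costs", "utilities", "run"),
                        "config")
  pars <- check_section(secs$parameters,
                        names(unclass(model_parameters())), "parameters")
  costs <- check_section(secs$costs, names(unclass(cost_schedule())), "costs")
  utils <- check_section(secs$utilities,
                         names(unclass(utility_schedule())), "utilities")
  run <- check_section(secs$run, names(default_run_settings()), "run")
  if (!run$analysis %in% c("primary", "secondary")) {
    abort("`run.analysis` must be \"primary\" or \"secondary\".")
  }
  check_nonneg(run$annual_rate, "run.annual_rate")
  check_nonneg(run$threshold, "run.threshold")
  default_config(
    parameters = do.call(model_parameters, pars),
    costs = do.call(cost_schedule, costs),
    utilities = do.call(utility_schedule, utils),
    run = run
  )
}

#' @rdname default_config
#' @param path Path to a YAML config file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  as_run_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  config <- as_run_config(config)
  out <- list(
    parameters = unclass(config$parameters),
    costs = unclass(config$costs),
    utilities = unclass(config$utilities),
    run = config$run
  )
  yaml::write_yaml(out, path)
  invisible(config)
}

#' @rdname default_config
#' @export
config_hash <- function(config) {
  config <- as_run_config(config)
  rlang::hash(list(unclass(config$parameters), unclass(config$costs),
                   unclass(config$utilities), config$run))
}

resolve_life_tables <- function(spec) {
  if (identical(spec, "synthetic")) {
    list(male = synthetic_life_table("male"),
         female = synthetic_life_table("female"))
  } else if (is.list(spec) && all(c("male", "female") %in% names(spec))) {
    list(male = read_life_table(spec$male),
         female = read_life_table(spec$female))
  } else {
    abort(paste0("`run.life_tables` must be \"synthetic\" or a list with ",
                 "`male` and `female` file paths."))
  }
}

#' Run the pipeline from a configuration object
#'
#' @param config A `run_config` (or a path handled by [load_config()]).
#' @return A [run_cea()] result.
#' @export
run_cea_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  config <- as_run_config(config)
  run_cea(
    params = config$parameters,
    costs = config$costs,
    utilities = config$utilities,
    life_tables = resolve_life_tables(config$run$life_tables),
    analysis = config$run$analysis,
    annual_rate = config$run$annual_rate,
    threshold = config$run$threshold
  )
}
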