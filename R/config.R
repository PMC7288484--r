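# YAML run configuration: schema validation, design construction, and
# round-trip serialisation. The CLI (inst/cli/bayesadapt) is a thin wrapper
# over these functions.

tte_design_keys <- c("total_events", "interim_events", "interim_rule",
                     "efficacy_threshold", "futility_threshold",
                     "final_threshold", "prior_mean", "prior_variance",
                     "look_dependence", "variance_factor")
binary_design_keys <- c("n_max", "n_interims", "schedule",
                        "efficacy_threshold", "futility_threshold",
                        "final_threshold", "prior_control_alpha",
                        "prior_control_beta", "prior_intervention_alpha",
                        "prior_intervention_beta", "accrual_rate",
                        "followup_days", "n_imputations", "dropout_rate")

#' Parse and validate a YAML run configuration
#'
#' A run configuration describes one design (`endpoint: tte` or
#' `endpoint: binary` plus a `design:` block whose keys mirror the
#' [tte_design()] / [binary_design()] arguments), a list of true-effect
#' `scenarios`, the replication count `n_sims`, the master `seed`, and
#' optional `output:` paths (`csv`, `json`). Validation is aggregated: all
#' schema violations are reported in a single error, not one at a time.
#'
#' @param path Path to a YAML file. Shipped examples live under
#'   `system.file("configs", package = "bayesadapt")`.
#' @return A list of class `"run_config"` with elements `endpoint`,
#'   `design` (a constructed design object), `scenarios`, `n_sims`, `seed`,
#'   and `output`.
#' @examples
#' cfg <- parse_config(system.file("configs", "cs1_efficacy.yaml",
#'                                 package = "bayesadapt"))
#' cfg$design
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  known_top <- c("endpoint", "design", "scenarios", "n_sims", "seed",
                 "output")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) note("unknown top-level keys: ",
                          paste(extra, collapse = ", "))

  endpoint <- raw$endpoint
  if (is.null(endpoint) || !endpoint %in% c("tte", "binary"))
    note("`endpoint` must be 'tte' or 'binary'")

  design <- NULL
  if (is.null(raw$design) || !is.list(raw$design)) {
    note("`design` block is required")
  } else if (!is.null(endpoint) && endpoint %in% c("tte", "binary")) {
    keys <- if (endpoint == "tte") tte_design_keys else binary_design_keys
    extra <- setdiff(names(raw$design), keys)
    if (length(extra)) note("unknown design keys: ",
                            paste(extra, collapse = ", "))
    design <- tryCatch(build_design(endpoint, raw$design),
                       error = function(e) {
                         note("design: ", conditionMessage(e))
                         NULL
                       })
  }

  scenarios <- NULL
  if (is.null(raw$scenarios) || length(raw$scenarios) == 0L) {
    note("`scenarios` must be a non-empty list")
  } else if (!is.null(endpoint) && endpoint %in% c("tte", "binary")) {
    scenarios <- tryCatch(build_scenarios(endpoint, raw$scenarios),
                          error = function(e) {
                            note("scenarios: ", conditionMessage(e))
                            NULL
                          })
  }

  n_sims <- raw$n_sims
  if (is.null(n_sims) || !is.numeric(n_sims) || n_sims < 1 ||
      n_sims != round(n_sims))
    note("`n_sims` must be a positive whole number")

  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || seed != round(seed))
    note("`seed` must be a whole number")

  output <- raw$output %||% list()
  if (length(setdiff(names(output), c("csv", "json"))))
    note("`output` accepts only 'csv' and 'json' keys")

  if (length(problems))
    stop_invalid("invalid run configuration:\n  - ",
                 paste(problems, collapse = "\n  - "))

  structure(list(endpoint = endpoint, design = design,
                 scenarios = scenarios,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 output = output),
            class = "run_config")
}

build_design <- function(endpoint, d) {
  if (endpoint == "tte") {
    tte_design(
      total_events = d$total_events %||% 200,
      interim_events = d$interim_events %||% ((d$total_events %||% 200) / 2),
      interim_rule = d$interim_rule %||% "none",
      efficacy_threshold = d$efficacy_threshold %||% 0.9,
      futility_threshold = d$futility_threshold %||% 0.5,
      final_threshold = d$final_threshold %||% 0.9,
      prior = normal_posterior(d$prior_mean %||% 0,
                               d$prior_variance %||% 1e4),
      look_dependence = d$look_dependence %||% "independent",
      variance_factor = d$variance_factor %||% 4
    )
  } else {
    binary_design(
      n_max = d$n_max %||% 1334,
      n_interims = d$n_interims %||% 0,
      schedule = d$schedule,
      efficacy_threshold = d$efficacy_threshold,
      futility_threshold = d$futility_threshold,
      final_threshold = d$final_threshold %||% 0.98,
      prior_control = beta_posterior(d$prior_control_alpha %||% 1,
                                     d$prior_control_beta %||% 1),
      prior_intervention = beta_posterior(d$prior_intervention_alpha %||% 1,
                                          d$prior_intervention_beta %||% 1),
      accrual_rate = d$accrual_rate %||% 2,
      followup_days = d$followup_days %||% 28,
      n_imputations = d$n_imputations %||% 500,
      dropout_rate = d$dropout_rate %||% 0
    )
  }
}

build_scenarios <- function(endpoint, raw) {
  if (endpoint == "tte") {
    hrs <- vapply(raw, function(s) {
      if (is.numeric(s) && length(s) == 1L) return(as.numeric(s))
      if (is.list(s) && !is.null(s$hr)) return(as.numeric(s$hr))
      stop_invalid("each tte scenario must be a number or have an `hr` key")
    }, numeric(1))
    if (any(hrs <= 0)) stop_invalid("hazard ratios must be positive")
    hrs
  } else {
    lapply(raw, function(s) {
      if (!is.list(s) || is.null(s$p_control) || is.null(s$p_intervention))
        stop_invalid("each binary scenario needs p_control and ",
                     "p_intervention")
      binary_scenario(s$p_control, s$p_intervention, label = s$label)
    })
  }
}

# Plain-list echo of a design, suitable for YAML/JSON serialisation and for
# re-parsing into an identical design.
design_as_config <- function(design) {
  if (inherits(design, "tte_design")) {
    list(total_events = design$total_events,
         interim_events = design$interim_events,
         interim_rule = design$interim_rule,
         efficacy_threshold = design$efficacy_threshold,
         futility_threshold = design$futility_threshold,
         final_threshold = design$final_threshold,
         prior_mean = design$prior$mean,
         prior_variance = design$prior$variance,
         look_dependence = design$look_dependence,
         variance_factor = design$variance_factor)
  } else if (inherits(design, "binary_design")) {
    out <- list(n_max = design$n_max,
                schedule = design$schedule,
                efficacy_threshold = design$efficacy_threshold,
                futility_threshold = design$futility_threshold,
                final_threshold = design$final_threshold,
                prior_control_alpha = design$prior_control$alpha,
                prior_control_beta = design$prior_control$beta,
                prior_intervention_alpha = design$prior_intervention$alpha,
                prior_intervention_beta = design$prior_intervention$beta,
                accrual_rate = design$accrual_rate,
                followup_days = design$followup_days,
                n_imputations = design$n_imputations,
                dropout_rate = design$dropout_rate)
    out[!vapply(out, is.null, logical(1))]
  } else {
    stop_invalid("unsupported design class")
  }
}

#' Serialise a run configuration back to YAML
#'
#' Inverse of [parse_config()]: a configuration written with
#' `write_run_config()` parses back to an identical `run_config`.
#'
#' @param config A `"run_config"` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config"))
    stop_invalid("`config` must be a run_config object")
  scenarios <- if (config$endpoint == "tte") {
    lapply(config$scenarios, function(hr) list(hr = hr))
  } else {
    lapply(config$scenarios, function(s)
      list(p_control = s$p_control, p_intervention = s$p_intervention,
           label = s$label))
  }
  payload <- list(endpoint = config$endpoint,
                  design = design_as_config(config$design),
                  scenarios = scenarios,
                  n_sims = config$n_sims,
                  seed = config$seed)
  if (length(config$output)) payload$output <- config$output
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (", x$endpoint, " endpoint): ",
      format(x$n_sims, big.mark = ","), " sims, seed ", x$seed, "\n\n",
      sep = "")
  print(x$design)
  invisible(x)
}

#' Execute a parsed run configuration
#'
#' Runs [run_oc()] for the configured design and scenarios and writes any
#' configured CSV/JSON outputs.
#'
#' @param config A `"run_config"` from [parse_config()].
#' @param n_sims,seed Optional overrides of the configured values.
#' @return The `"trial_oc"` result, invisibly printed by the CLI.
#' @export
run_config <- function(config, n_sims = NULL, seed = NULL) {
  if (!inherits(config, "run_config"))
    stop_invalid("`config` must be a run_config object")
  oc <- run_oc(config$design,
               scenarios = config$scenarios,
               n_sims = n_sims %||% config$n_sims,
               seed = seed %||% config$seed)
  if (!is.null(config$output$csv)) write_oc_csv(oc, config$output$csv)
  if (!is.null(config$output$json)) write_oc_json(oc, config$output$json)
  oc
}
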