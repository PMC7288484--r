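#' Evenly spaced interim schedule by patients recruited
#'
#' Places the k-th of `n_interims` looks after `round(k * n_max /
#' (n_interims + 1))` patients have been recruited, rounding halves up
#' (1334 with 3 looks gives 334, 667, 1001). The final analysis is always at
#' `n_max` and is not part of the returned schedule.
#'
#' @param n_max Maximum (final) sample size.
#' @param n_interims Number of interim analyses (>= 0).
#' @return Integer vector of recruitment counts, strictly increasing;
#'   empty for `n_interims = 0`.
#' @examples
#' build_even_schedule(1334, 3) # 334 667 1001
#' @export
build_even_schedule <- function(n_max, n_interims) {
  n_max <- check_count(n_max, "n_max", lower = 2L)
  n_interims <- check_count(n_interims, "n_interims")
  if (n_interims == 0L) return(integer(0))
  k <- seq_len(n_interims)
  sched <- as.integer(floor(k * n_max / (n_interims + 1) + 0.5))
  if (anyDuplicated(sched) || any(sched >= n_max) || any(sched < 1L))
    stop_invalid("`n_interims` too large: rounding collapses looks for ",
                 "n_max = ", n_max)
  sched
}

#' True outcome rates for a binary-endpoint scenario
#'
#' @param p_control,p_intervention True event (e.g. 28-day mortality) rates
#'   in (0, 1). Defaults are the null scenario of the lung-injury trial
#'   redesign: 44\% mortality in both arms. The target-effect scenario is
#'   `binary_scenario(0.44, 0.35)`, a 9 percentage-point absolute reduction.
#' @param label Optional scenario label used in output tables.
#' @return An object of class `"binary_scenario"`.
#' @export
binary_scenario <- function(p_control = 0.44, p_intervention = 0.44,
                            label = NULL) {
  check_number(p_control, "p_control", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(p_intervention, "p_intervention", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(label)) {
    label <- if (p_control == p_intervention) "null" else
      sprintf("%.0f%% vs %.0f%%", 100 * p_intervention, 100 * p_control)
  }
  structure(list(p_control = p_control, p_intervention = p_intervention,
                 label = label),
            class = "binary_scenario")
}

#' Binary-endpoint Bayesian adaptive design with predictive stopping
#'
#' Describes a two-arm 1:1 trial with a binary outcome observed
#' `followup_days` after enrolment, independent beta posteriors per arm, and
#' interim analyses at fixed recruitment counts. At each interim the design
#' may stop early:
#' \itemize{
#'   \item for efficacy, if the posterior predictive probability of success
#'     at the \emph{current} sample size (`P_curr`) exceeds
#'     `efficacy_threshold` (default 0.99);
#'   \item for futility, if the posterior predictive probability of success
#'     at the \emph{maximum} sample size (`P_max`) falls below
#'     `futility_threshold` (default 0.10).
#' }
#' Setting a threshold to `NULL` disables that rule. A trial reaching
#' `n_max` is successful if Pr(theta_intervention < theta_control | data)
#' exceeds `final_threshold` (default 0.98). All inequalities are strict.
#'
#' Patients enrolled but without completed follow-up at an interim have
#' their outcomes imputed from the current beta posteriors (a beta-binomial
#' predictive draw); for `P_max`, not-yet-enrolled patients are imputed the
#' same way. Accrual is deterministic at `accrual_rate` patients/day, so at
#' any interim the most recent `accrual_rate * followup_days` recruits lack
#' follow-up. The accrual rate is a design assumption, not a reported trial
#' quantity; its default of 2/day leaves 56 patients incomplete at each
#' look.
#'
#' @param n_max Maximum sample size (even; default 1334, i.e. 667 per arm).
#' @param n_interims Number of evenly spaced interims (used when `schedule`
#'   is `NULL`); see [build_even_schedule()].
#' @param schedule Explicit interim recruitment counts (overrides
#'   `n_interims`).
#' @param efficacy_threshold Stop if `P_curr` > this, or `NULL` to disable.
#' @param futility_threshold Stop if `P_max` < this, or `NULL` to disable.
#' @param final_threshold Final success bar on the posterior superiority
#'   probability.
#' @param prior_control,prior_intervention [beta_posterior()] priors
#'   (default uniform Beta(1, 1)).
#' @param accrual_rate Patients enrolled per day (deterministic).
#' @param followup_days Delay until the outcome is observed (default 28).
#' @param n_imputations Predictive draws per interim probability.
#' @param dropout_rate Proportion of patients lost to follow-up, removed
#'   from both numerator and denominator (default 0).
#' @return An object of class `"binary_design"`.
#' @examples
#' # Efficacy-only redesign with looks at 334, 667, 1001 of 1334 patients:
#' binary_design(n_interims = 3, futility_threshold = NULL)
#' @export
binary_design <- function(n_max = 1334,
                          n_interims = 0,
                          schedule = NULL,
                          efficacy_threshold = 0.99,
                          futility_threshold = 0.10,
                          final_threshold = 0.98,
                          prior_control = beta_posterior(1, 1),
                          prior_intervention = beta_posterior(1, 1),
                          accrual_rate = 2,
                          followup_days = 28,
                          n_imputations = 500,
                          dropout_rate = 0) {
  n_max <- check_count(n_max, "n_max", lower = 2L)
  if (n_max %% 2L != 0L)
    stop_invalid("`n_max` must be even (1:1 allocation in blocks of 2)")
  if (is.null(schedule)) {
    schedule <- build_even_schedule(n_max, n_interims)
  } else {
    schedule <- vapply(schedule, check_count, integer(1), name = "schedule")
    if (is.unsorted(schedule, strictly = TRUE))
      stop_invalid("`schedule` must be strictly increasing")
    if (length(schedule) && (schedule[1] < 1L || max(schedule) >= n_max))
      stop_invalid("`schedule` entries must lie in [1, n_max)")
  }
  for (nm in c("efficacy_threshold", "futility_threshold")) {
    val <- get(nm)
    if (!is.null(val))
      check_number(val, nm, lower = 0, upper = 1)
  }
  check_number(final_threshold, "final_threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (!inherits(prior_control, "beta_posterior") ||
      !inherits(prior_intervention, "beta_posterior"))
    stop_invalid("arm priors must be beta_posterior objects")
  check_number(accrual_rate, "accrual_rate", lower = 0, strict_lower = TRUE)
  followup_days <- check_number(followup_days, "followup_days", lower = 0)
  n_imputations <- check_count(n_imputations, "n_imputations", lower = 1L)
  check_number(dropout_rate, "dropout_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  structure(list(endpoint = "binary",
                 n_max = n_max,
                 schedule = as.integer(schedule),
                 efficacy_threshold = efficacy_threshold,
                 futility_threshold = futility_threshold,
                 final_threshold = final_threshold,
                 prior_control = prior_control,
                 prior_intervention = prior_intervention,
                 accrual_rate = accrual_rate,
                 followup_days = followup_days,
                 n_imputations = n_imputations,
                 dropout_rate = dropout_rate),
            class = "binary_design")
}

#' @export
print.binary_design <- function(x, ...) {
  cat("Two-arm Bayesian binary-endpoint design (beta-binomial monitoring)\n")
  cat(sprintf("  Maximum sample size %d (1:1); final success if Pr(theta_i < theta_c | data) > %g\n",
              x$n_max, x$final_threshold))
  if (length(x$schedule)) {
    cat(sprintf("  Interims after %s recruits\n",
                paste(x$schedule, collapse = ", ")))
    if (!is.null(x$efficacy_threshold))
      cat(sprintf("    efficacy stop if P_curr > %g\n", x$efficacy_threshold))
    if (!is.null(x$futility_threshold))
      cat(sprintf("    futility stop if P_max < %g\n", x$futility_threshold))
  } else {
    cat("  Fixed design (no interim analyses)\n")
  }
  cat(sprintf("  Priors: control Beta(%g, %g), intervention Beta(%g, %g)\n",
              x$prior_control$alpha, x$prior_control$beta,
              x$prior_intervention$alpha, x$prior_intervention$beta))
  cat(sprintf("  Accrual %g/day, %g-day follow-up, %d imputations/interim\n",
              x$accrual_rate, x$followup_days, x$n_imputations))
  invisible(x)
}

#' Snapshot of an accruing binary trial at an analysis time
#'
#' Per-arm enrolment, completed follow-up, and observed events among
#' completers — the sufficient state for computing interim predictive
#' probabilities.
#'
#' @param enrolled,completed,events Length-2 integer vectors (control,
#'   intervention); `events <= completed <= enrolled` elementwise.
#' @return An object of class `"trial_state"`.
#' @export
trial_state <- function(enrolled, completed, events) {
  for (v in list(enrolled, completed, events))
    if (length(v) != 2L || any(v < 0) || any(v != round(v)))
      stop_invalid("state fields must be length-2 non-negative counts")
  if (any(completed > enrolled))
    stop_invalid("completed follow-up cannot exceed enrolment")
  if (any(events > completed))
    stop_invalid("events cannot exceed completed follow-up")
  structure(list(enrolled = as.integer(enrolled),
                 completed = as.integer(completed),
                 events = as.integer(events)),
            class = "trial_state")
}
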