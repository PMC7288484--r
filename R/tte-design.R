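#' Time-to-event adaptive design monitored on the log hazard ratio
#'
#' Describes a two-arm trial whose single monitored quantity is the hazard
#' ratio, analysed through a normal-normal conjugate model for the log HR at
#' a fixed number of events. The design runs to `total_events` events with an
#' optional single interim analysis at `interim_events`, at which the trial
#' may stop early for futility (continue only if Pr(HR < 1 | data) is at
#' least `futility_threshold`) or for efficacy (stop if Pr(HR < 1 | data)
#' exceeds `efficacy_threshold`). At the final analysis the trial is
#' successful if Pr(HR < 1 | data) exceeds `final_threshold`.
#'
#' No patient-level survival times are generated: the estimated log HR at
#' `d` events is drawn directly from a normal distribution with mean
#' `log(true_hr)` and variance `variance_factor / d` (the usual 4/d
#' approximation under 1:1 allocation).
#'
#' @section Dependence between looks:
#' `look_dependence` controls how the interim and final estimates relate.
#' `"independent"` draws the two estimates independently — the default,
#' because it is what a direct per-look sampling scheme produces and it
#' admits a simple closed form for the success probability (see
#' [analytic_success_probability()]); e.g. with threshold b at two
#' efficacy looks the null success probability is exactly 1 - b^2.
#' `"correlated"` uses the canonical group-sequential accumulating-data
#' structure: the final score statistic is the interim score plus an
#' independent increment, with information d/4 at d events.
#'
#' @param total_events Events at the final analysis (default 200).
#' @param interim_events Events at the interim look (default half the total).
#' @param interim_rule One of `"none"`, `"futility"`, `"efficacy"`.
#' @param efficacy_threshold Stop early if Pr(HR < 1 | data) > this (0.9).
#' @param futility_threshold Stop early if Pr(HR < 1 | data) < this (0.5);
#'   a posterior probability exactly at the threshold continues.
#' @param final_threshold Success at the final analysis requires
#'   Pr(HR < 1 | data) > this (0.9).
#' @param prior [normal_posterior()] prior on the log HR; default vague
#'   N(0, 10000).
#' @param look_dependence `"independent"` or `"correlated"`.
#' @param variance_factor Numerator of the log-HR variance approximation
#'   (4 for equal allocation and follow-up).
#' @return An object of class `"tte_design"`.
#' @examples
#' tte_design(interim_rule = "efficacy")
#' @export
tte_design <- function(total_events = 200,
                       interim_events = total_events / 2,
                       interim_rule = c("none", "futility", "efficacy"),
                       efficacy_threshold = 0.9,
                       futility_threshold = 0.5,
                       final_threshold = 0.9,
                       prior = normal_posterior(0, 1e4),
                       look_dependence = c("independent", "correlated"),
                       variance_factor = 4) {
  interim_rule <- match.arg(interim_rule)
  look_dependence <- match.arg(look_dependence)
  total_events <- check_count(total_events, "total_events", lower = 1L)
  interim_events <- check_count(interim_events, "interim_events", lower = 1L)
  if (interim_events >= total_events)
    stop_invalid("`interim_events` must be < `total_events`")
  check_number(efficacy_threshold, "efficacy_threshold",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(futility_threshold, "futility_threshold",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(final_threshold, "final_threshold",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(variance_factor, "variance_factor",
               lower = 0, strict_lower = TRUE)
  if (!inherits(prior, "normal_posterior"))
    stop_invalid("`prior` must be a normal_posterior object")
  structure(list(endpoint = "tte",
                 total_events = total_events,
                 interim_events = interim_events,
                 interim_rule = interim_rule,
                 efficacy_threshold = efficacy_threshold,
                 futility_threshold = futility_threshold,
                 final_threshold = final_threshold,
                 prior = prior,
                 look_dependence = look_dependence,
                 variance_factor = variance_factor),
            class = "tte_design")
}

#' @export
print.tte_design <- function(x, ...) {
  cat("Two-arm Bayesian time-to-event design (log-HR monitoring)\n")
  cat(sprintf("  Final analysis at %d events: success if Pr(HR<1|data) > %g\n",
              x$total_events, x$final_threshold))
  if (x$interim_rule == "none") {
    cat("  No interim analysis\n")
  } else if (x$interim_rule == "efficacy") {
    cat(sprintf("  Interim at %d events: stop for efficacy if Pr(HR<1|data) > %g\n",
                x$interim_events, x$efficacy_threshold))
  } else {
    cat(sprintf("  Interim at %d events: stop for futility if Pr(HR<1|data) < %g\n",
                x$interim_events, x$futility_threshold))
  }
  cat(sprintf("  Prior on log HR: N(%g, %g); looks %s\n",
              x$prior$mean, x$prior$variance, x$look_dependence))
  invisible(x)
}
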