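#' Conjugate posteriors for two-arm trial monitoring
#'
#' The two endpoint models used throughout the package are fully conjugate,
#' so interim analyses reduce to closed-form posterior updates:
#' \itemize{
#'   \item a normal posterior for the log hazard ratio (normal likelihood for
#'     the estimated log HR with known sampling variance, normal prior), and
#'   \item independent beta posteriors for the per-arm event rates of a
#'     binary endpoint (binomial likelihood, beta prior).
#' }
#'
#' `normal_posterior()` and `beta_posterior()` construct validated posterior
#' (or prior) objects; the `update_*` functions fold in new data.
#'
#' @param mean Posterior mean of the log hazard ratio.
#' @param variance Posterior variance of the log hazard ratio; must be
#'   strictly positive. The package-wide vague default is variance 10000
#'   centred at 0, which contributes negligible information next to even a
#'   handful of events.
#' @return `normal_posterior()` returns an object of class
#'   `"normal_posterior"` with fields `mean` and `variance`.
#' @examples
#' vague <- normal_posterior(0, 1e4)
#' post <- update_normal(vague, estimate = log(0.7), estimate_variance = 0.02)
#' prob_hr_below_one(post)
#' @export
normal_posterior <- function(mean = 0, variance = 1e4) {
  check_number(mean, "mean")
  check_number(variance, "variance", lower = 0, strict_lower = TRUE)
  structure(list(mean = mean, variance = variance),
            class = "normal_posterior")
}

#' @export
print.normal_posterior <- function(x, ...) {
  cat(sprintf("Normal posterior for log HR: mean %.5g, variance %.5g\n",
              x$mean, x$variance))
  invisible(x)
}

#' Precision-weighted normal-normal conjugate update
#'
#' Combines a normal prior on the log hazard ratio with a normally
#' distributed estimate of known sampling variance. The posterior precision
#' is the sum of the prior and data precisions and the posterior mean their
#' precision-weighted average.
#'
#' @param prior A [normal_posterior()] object.
#' @param estimate Estimated log hazard ratio.
#' @param estimate_variance Sampling variance of the estimate (> 0).
#' @return The updated `"normal_posterior"`.
#' @export
update_normal <- function(prior, estimate, estimate_variance) {
  if (!inherits(prior, "normal_posterior"))
    stop_invalid("`prior` must be a normal_posterior object")
  check_number(estimate, "estimate")
  check_number(estimate_variance, "estimate_variance",
               lower = 0, strict_lower = TRUE)
  prior_prec <- 1 / prior$variance
  data_prec <- 1 / estimate_variance
  post_var <- 1 / (prior_prec + data_prec)
  post_mean <- (prior$mean * prior_prec + estimate * data_prec) * post_var
  normal_posterior(post_mean, post_var)
}

#' Posterior probability that the hazard ratio is below one
#'
#' The monitored quantity in the time-to-event design: the lower-tail
#' probability of the log-HR posterior at zero, i.e. Pr(HR < 1 | data).
#'
#' @param posterior A [normal_posterior()] object.
#' @return A probability in \[0, 1\].
#' @export
prob_hr_below_one <- function(posterior) {
  if (!inherits(posterior, "normal_posterior"))
    stop_invalid("`posterior` must be a normal_posterior object")
  stats::pnorm(0, mean = posterior$mean, sd = sqrt(posterior$variance))
}

#' Beta posterior for a binomial event rate
#'
#' @param alpha,beta Strictly positive shape parameters. `Beta(1, 1)` is the
#'   uniform prior used by default for both arms of the binary design.
#' @return An object of class `"beta_posterior"` with fields `alpha`, `beta`.
#' @examples
#' update_beta(beta_posterior(1, 1), events = 10, patients = 20)
#' @export
beta_posterior <- function(alpha = 1, beta = 1) {
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  structure(list(alpha = alpha, beta = beta), class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta posterior: Beta(%.5g, %.5g), mean %.4f\n",
              x$alpha, x$beta, x$alpha / (x$alpha + x$beta)))
  invisible(x)
}

#' Beta-binomial conjugate update
#'
#' Adds `events` to the first shape and `patients - events` to the second.
#'
#' @param prior A [beta_posterior()] object.
#' @param events Number of events observed (0 <= events <= patients).
#' @param patients Number of patients with completed follow-up.
#' @return The updated `"beta_posterior"`.
#' @export
update_beta <- function(prior, events, patients) {
  if (!inherits(prior, "beta_posterior"))
    stop_invalid("`prior` must be a beta_posterior object")
  events <- check_count(events, "events")
  patients <- check_count(patients, "patients")
  if (events > patients)
    stop_invalid("`events` (", events, ") cannot exceed `patients` (",
                 patients, ")")
  beta_posterior(prior$alpha + events, prior$beta + (patients - events))
}

# Pr(X < Y) for X ~ Beta(a, b), Y ~ Beta(c, d), all shapes integer.
# Finite-sum identity; each term is evaluated on the log scale for stability.
beta_less_exact <- function(a, b, c, d) {
  j <- seq_len(c) - 1
  sum(exp(lbeta(a + j, b + d) - log(d + j) - lbeta(1 + j, d) - lbeta(a, b)))
}

# Quadrature fallback for non-integer shapes:
# Pr(X < Y) = E_X[ 1 - F_Y(X) ].
beta_less_quadrature <- function(a, b, c, d) {
  f <- function(x) stats::dbeta(x, a, b) * stats::pbeta(x, c, d,
                                                        lower.tail = FALSE)
  stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 500L)$value
}

#' Posterior probability that the intervention arm has the lower event rate
#'
#' Computes Pr(theta_intervention < theta_control) for two independent beta
#' posteriors — the superiority probability used both for final-analysis
#' success and inside the predictive-probability stopping rules. When all
#' four shape parameters are integers (always the case with integer-shape
#' priors and observed counts) the exact finite-sum identity is used;
#' otherwise adaptive quadrature, accurate to better than 1e-8 absolute.
#'
#' @param control,intervention [beta_posterior()] objects for the two arms.
#' @return Pr(theta_intervention < theta_control), a probability in \[0, 1\].
#' @examples
#' prob_superiority(beta_posterior(2, 1), beta_posterior(1, 2)) # 5/6
#' @export
prob_superiority <- function(control, intervention) {
  if (!inherits(control, "beta_posterior") ||
      !inherits(intervention, "beta_posterior"))
    stop_invalid("both arms must be beta_posterior objects")
  a <- intervention$alpha; b <- intervention$beta
  c <- control$alpha;      d <- control$beta
  shapes <- c(a, b, c, d)
  p <- if (all(shapes == round(shapes))) {
    beta_less_exact(a, b, c, d)
  } else {
    beta_less_quadrature(a, b, c, d)
  }
  min(max(p, 0), 1)
}

#' One draw from the beta-binomial posterior predictive
#'
#' Draws a rate from the beta posterior, then an event count from a binomial
#' with that rate — the predictive distribution used to impute outcomes for
#' patients without completed follow-up and for patients not yet enrolled.
#'
#' @param posterior A [beta_posterior()] object.
#' @param n_future Number of future (unobserved) patients; >= 0.
#' @param n_draws Number of independent predictive draws to return.
#' @return Integer vector of length `n_draws`, each in \[0, n_future\].
#' @export
sample_predictive_events <- function(posterior, n_future, n_draws = 1L) {
  if (!inherits(posterior, "beta_posterior"))
    stop_invalid("`posterior` must be a beta_posterior object")
  n_future <- check_count(n_future, "n_future")
  n_draws <- check_count(n_draws, "n_draws", lower = 1L)
  if (n_future == 0L) return(integer(n_draws))
  theta <- stats::rbeta(n_draws, posterior$alpha, posterior$beta)
  stats::rbinom(n_draws, n_future, theta)
}
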