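# Predictive-probability machinery and the vectorised binary-trial engine.
#
# The expensive primitive at an interim is "does this imputed completed
# dataset clear the final posterior bar?". Because the final rule depends on
# the data only through the per-arm event totals, the indicator is a table
# lookup once we know, for each control event total s_c, the largest
# intervention event total that still satisfies
# Pr(theta_i < theta_c | data) > bar. That critical count is found by binary
# search (the superiority probability is decreasing in intervention events)
# and memoised across trials, imputations and looks.

beta_less_prob <- function(ai, bi, ac, bc) {
  shapes <- c(ai, bi, ac, bc)
  if (all(shapes == round(shapes))) beta_less_exact(ai, bi, ac, bc)
  else beta_less_quadrature(ai, bi, ac, bc)
}

# Largest s_i in [0, n_i] with Pr(theta_i < theta_c) > bar given s_c control
# events out of n_c; -1 if none. Scalar arguments.
critical_events <- function(s_c, n_c, n_i, bar, prior_c, prior_i) {
  f <- function(s_i) {
    beta_less_prob(prior_i$alpha + s_i, prior_i$beta + n_i - s_i,
                   prior_c$alpha + s_c, prior_c$beta + n_c - s_c)
  }
  ans <- -1L
  lo <- 0L; hi <- as.integer(n_i)
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (f(mid) > bar) { ans <- mid; lo <- mid + 1L } else hi <- mid - 1L
  }
  ans
}

# Vectorised, cached critical-count lookup. s_c, n_c, n_i may be vectors or
# matrices (recycled against each other); returns the same shape as s_c.
# Triples are packed into an exact double key (counts are far below 2^14)
# so deduplication stays cheap on multi-million-element imputation matrices.
critical_events_lookup <- function(s_c, n_c, n_i, bar, prior_c, prior_i,
                                   cache = new.env(parent = emptyenv())) {
  b <- 16384
  key <- (as.vector(n_c) * b + as.vector(n_i)) * b + as.vector(s_c)
  if (length(key) < length(s_c)) key <- rep_len(key, length(s_c))
  uk <- unique(key)
  uval <- vapply(uk, function(k) {
    id <- as.character(k)
    hit <- cache[[id]]
    if (!is.null(hit)) return(hit)
    sc <- k %% b
    ni <- (k %/% b) %% b
    nc <- k %/% (b * b)
    val <- critical_events(sc, nc, ni, bar, prior_c, prior_i)
    cache[[id]] <- val
    val
  }, numeric(1))
  out <- uval[match(key, uk)]
  if (is.matrix(s_c)) dim(out) <- dim(s_c)
  out
}

# Success indicator for completed per-arm totals (vectorised).
final_success_indicator <- function(s_c, s_i, n_c, n_i, design, cache) {
  crit <- critical_events_lookup(s_c, n_c, n_i, design$final_threshold,
                                 design$prior_control,
                                 design$prior_intervention, cache)
  s_i <= crit
}

# Shared imputation core: given per-trial posterior counts and the number of
# outcomes still to impute per arm, draw `n_imp` beta-binomial completions
# and return the per-trial fraction clearing the final bar at evaluation
# sample sizes (n_eval_c, n_eval_i). All count arguments are vectors over
# trials (scalars recycle).
predictive_success_fraction <- function(s_c, n_obs_c, s_i, n_obs_i,
                                        add_c, add_i, n_eval_c, n_eval_i,
                                        design, n_imp, cache) {
  n <- max(length(s_c), length(s_i))
  pr_c <- design$prior_control
  pr_i <- design$prior_intervention
  theta_c <- stats::rbeta(n * n_imp, pr_c$alpha + s_c,
                          pr_c$beta + n_obs_c - s_c)
  x_c <- stats::rbinom(n * n_imp, add_c, theta_c)
  theta_i <- stats::rbeta(n * n_imp, pr_i$alpha + s_i,
                          pr_i$beta + n_obs_i - s_i)
  x_i <- stats::rbinom(n * n_imp, add_i, theta_i)
  sc_tot <- matrix(s_c + x_c, n, n_imp)
  si_tot <- matrix(s_i + x_i, n, n_imp)
  ind <- final_success_indicator(sc_tot, si_tot, n_eval_c, n_eval_i,
                                 design, cache)
  dim(ind) <- c(n, n_imp)
  rowMeans(ind)
}

#' Posterior predictive probability of success at the current sample size
#'
#' `P_curr`: the probability, under the current beta posteriors, that the
#' trial would meet its final success criterion if it stopped enrolling now
#' and the enrolled-but-incomplete patients' outcomes were observed.
#' Incomplete outcomes are imputed by beta-binomial predictive draws; the
#' returned value is the fraction of `n_imputations` imputed completions
#' clearing the final bar. With no incomplete patients it is exactly the 0/1
#' current success indicator. Used for efficacy stopping (stop if
#' `P_curr` > `efficacy_threshold`).
#'
#' @param state A [trial_state()].
#' @param design A [binary_design()].
#' @param n_imputations Number of predictive draws (defaults to the
#'   design's).
#' @return A probability in \[0, 1\].
#' @export
predictive_prob_success_current <- function(state, design,
                                            n_imputations = design$n_imputations) {
  check_state_design(state, design)
  add <- state$enrolled - state$completed
  cache <- new.env(parent = emptyenv())
  if (all(add == 0L)) {
    ok <- final_success_indicator(state$events[1], state$events[2],
                                  state$enrolled[1], state$enrolled[2],
                                  design, cache)
    return(as.numeric(ok))
  }
  mean(predictive_success_fraction(
    state$events[1], state$completed[1], state$events[2], state$completed[2],
    add[1], add[2], state$enrolled[1], state$enrolled[2],
    design, n_imputations, cache))
}

#' Posterior predictive probability of success at the maximum sample size
#'
#' `P_max`: as [predictive_prob_success_current()], but the imputation
#' extends to the design's maximum sample size — both the
#' enrolled-but-incomplete patients and all not-yet-enrolled patients up to
#' `n_max / 2` per arm are drawn from each arm's beta-binomial predictive.
#' Used for futility stopping (stop if `P_max` < `futility_threshold`).
#'
#' @inheritParams predictive_prob_success_current
#' @return A probability in \[0, 1\].
#' @export
predictive_prob_success_max <- function(state, design,
                                        n_imputations = design$n_imputations) {
  check_state_design(state, design)
  n_arm <- design$n_max %/% 2L
  if (any(state$enrolled > n_arm))
    stop_invalid("enrolment exceeds n_max/2 per arm")
  add <- n_arm - state$completed
  cache <- new.env(parent = emptyenv())
  if (all(add == 0L)) {
    ok <- final_success_indicator(state$events[1], state$events[2],
                                  n_arm, n_arm, design, cache)
    return(as.numeric(ok))
  }
  mean(predictive_success_fraction(
    state$events[1], state$completed[1], state$events[2], state$completed[2],
    add[1], add[2], n_arm, n_arm, design, n_imputations, cache))
}

check_state_design <- function(state, design) {
  if (!inherits(state, "trial_state"))
    stop_invalid("`state` must be a trial_state object")
  if (!inherits(design, "binary_design"))
    stop_invalid("`design` must be a binary_design object")
  if (sum(state$enrolled) == 0L)
    stop_invalid("trial state has no enrolled patients")
  invisible(TRUE)
}

# --- Vectorised trial engine ------------------------------------------------

# Per-trial control-arm size among the first k recruits, under permuted
# blocks of 2. For even k this is k/2 for every trial; for odd k the extra
# patient's arm is the block-level coin flip, drawn from a substream keyed by
# block index so that designs sharing a look position share the flip.
arm_split <- function(k, n_sims, seed) {
  base <- k %/% 2L
  if (k %% 2L == 0L) {
    list(n_c = rep.int(base, n_sims), n_i = rep.int(base, n_sims))
  } else {
    block <- (k + 1L) %/% 2L
    set.seed(mix_seed(seed, 22L, block))
    extra <- stats::runif(n_sims) < 0.5
    list(n_c = base + extra, n_i = k - (base + extra))
  }
}

row_cumsum <- function(m) {
  out <- t(apply(m, 1L, cumsum))
  dim(out) <- dim(m)
  out
}

# Value of a row-cumsum matrix at a per-row column index (0 -> 0).
ragged_at <- function(cum, idx) {
  out <- numeric(nrow(cum))
  pos <- idx > 0L
  out[pos] <- cum[cbind(which(pos), idx[pos])]
  out
}

simulate_binary_trials <- function(design, scenario, n_sims, seed) {
  n_arm <- design$n_max %/% 2L
  n_imp <- design$n_imputations
  lag <- as.integer(round(design$accrual_rate * design$followup_days))

  # Patient-level outcome streams, coupled across scenarios and shared
  # across designs run with the same seed (common random numbers).
  set.seed(mix_seed(seed, 21L))
  y_c <- matrix(stats::runif(n_sims * n_arm) < scenario$p_control,
                n_sims, n_arm)
  y_i <- matrix(stats::runif(n_sims * n_arm) < scenario$p_intervention,
                n_sims, n_arm)
  if (design$dropout_rate > 0) {
    set.seed(mix_seed(seed, 23L))
    k_c <- matrix(stats::runif(n_sims * n_arm) >= design$dropout_rate,
                  n_sims, n_arm)
    k_i <- matrix(stats::runif(n_sims * n_arm) >= design$dropout_rate,
                  n_sims, n_arm)
  } else {
    k_c <- k_i <- NULL
  }

  # Cumulative kept counts and kept-event counts per arm position.
  if (is.null(k_c)) {
    s_cum_c <- row_cumsum(y_c)
    s_cum_i <- row_cumsum(y_i)
    n_at <- function(cum_kept, idx) idx          # all patients kept
    n_cum_c <- n_cum_i <- NULL
  } else {
    s_cum_c <- row_cumsum(y_c & k_c)
    s_cum_i <- row_cumsum(y_i & k_i)
    n_cum_c <- row_cumsum(k_c)
    n_cum_i <- row_cumsum(k_i)
    n_at <- function(cum_kept, idx) ragged_at(cum_kept, idx)
  }

  active <- rep.int(TRUE, n_sims)
  stop_reason <- rep.int("final", n_sims)
  success <- rep.int(NA, n_sims)
  n_at_stop <- rep.int(design$n_max, n_sims)
  cache <- new.env(parent = emptyenv())

  for (k in design$schedule) {
    m <- min(max(k - lag, 0L), k)              # recruits with follow-up
    split_k <- arm_split(k, n_sims, seed)
    split_m <- arm_split(m, n_sims, seed)

    n_obs_c <- n_at(n_cum_c, split_m$n_c)
    n_obs_i <- n_at(n_cum_i, split_m$n_i)
    s_c <- ragged_at(s_cum_c, split_m$n_c)
    s_i <- ragged_at(s_cum_i, split_m$n_i)

    if (!is.null(design$efficacy_threshold)) {
      n_enr_c <- n_at(n_cum_c, split_k$n_c)
      n_enr_i <- n_at(n_cum_i, split_k$n_i)
      set.seed(mix_seed(seed, 31L, k))
      p_curr <- predictive_success_fraction(
        s_c, n_obs_c, s_i, n_obs_i,
        n_enr_c - n_obs_c, n_enr_i - n_obs_i,
        n_enr_c, n_enr_i, design, n_imp, cache)
      hit <- active & p_curr > design$efficacy_threshold
      stop_reason[hit] <- "efficacy"
      success[hit] <- TRUE
      n_at_stop[hit] <- k
      active <- active & !hit
    }
    if (!is.null(design$futility_threshold)) {
      n_fin_c <- n_at(n_cum_c, rep.int(n_arm, n_sims))
      n_fin_i <- n_at(n_cum_i, rep.int(n_arm, n_sims))
      set.seed(mix_seed(seed, 32L, k))
      p_max <- predictive_success_fraction(
        s_c, n_obs_c, s_i, n_obs_i,
        n_fin_c - n_obs_c, n_fin_i - n_obs_i,
        n_fin_c, n_fin_i, design, n_imp, cache)
      hit <- active & p_max < design$futility_threshold
      stop_reason[hit] <- "futility"
      success[hit] <- FALSE
      n_at_stop[hit] <- k
      active <- active & !hit
    }
  }

  # Final analysis for trials that ran to n_max with complete follow-up.
  n_fin_c <- n_at(n_cum_c, rep.int(n_arm, n_sims))
  n_fin_i <- n_at(n_cum_i, rep.int(n_arm, n_sims))
  fin_ok <- final_success_indicator(s_cum_c[, n_arm], s_cum_i[, n_arm],
                                    n_fin_c, n_fin_i, design, cache)
  success[active] <- fin_ok[active]

  data.frame(
    stopped_early = stop_reason != "final",
    stop_reason = factor(stop_reason,
                         levels = c("efficacy", "futility", "final")),
    success = as.logical(success),
    n_enrolled_at_stop = n_at_stop
  )
}

#' Simulate replicate trials from a binary-endpoint design
#'
#' Runs the patient-level engine: deterministic accrual, permuted-block 1:1
#' allocation, Bernoulli outcomes revealed after the follow-up delay,
#' predictive-probability interim rules, and the posterior-probability final
#' rule. Outcome streams are keyed by the seed and the scenario only, so two
#' designs simulated with the same seed and scenario see identical patients
#' (common random numbers); imputation streams are keyed by interim position
#' so designs sharing a look also share its imputation draws.
#'
#' @param object A [binary_design()].
#' @param nsim Number of replicate trials.
#' @param seed Integer master seed.
#' @param scenario A [binary_scenario()].
#' @param ... Unused.
#' @return A data frame with one row per trial: `stopped_early`,
#'   `stop_reason`, `success`, `n_enrolled_at_stop`.
#' @examples
#' d <- binary_design(n_max = 200, n_interims = 1, accrual_rate = 1,
#'                    n_imputations = 50)
#' res <- simulate(d, nsim = 50, seed = 1, scenario = binary_scenario())
#' mean(res$success)
#' @export
simulate.binary_design <- function(object, nsim = 1, seed = 1L,
                                   scenario = binary_scenario(), ...) {
  if (!inherits(scenario, "binary_scenario"))
    stop_invalid("`scenario` must be a binary_scenario object")
  nsim <- check_count(nsim, "nsim", lower = 1L)
  simulate_binary_trials(object, scenario, nsim, seed)
}

#' Simulate a single binary-endpoint trial
#'
#' @param design A [binary_design()].
#' @param scenario A [binary_scenario()].
#' @param seed Integer master seed.
#' @return A list with `stopped_early`, `stop_reason`, `success`,
#'   `n_enrolled_at_stop`.
#' @export
simulate_binary_trial <- function(design, scenario = binary_scenario(),
                                  seed = 1L) {
  res <- simulate(design, nsim = 1L, seed = seed, scenario = scenario)
  as.list(res[1L, ])
}
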