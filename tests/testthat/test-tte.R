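test_that("log-HR estimator draws have the stated mean and variance", {
  out <- sample_loghr_estimate(1, 100)
  expect_equal(out$variance, 0.04)

  set.seed(3)
  out <- sample_loghr_estimate(0.7, 200, n = 1e5)
  expect_equal(out$variance, 0.02)
  expect_lt(abs(mean(out$estimate) - log(0.7)), 3 * sqrt(0.02 / 1e5))
  expect_lt(abs(var(out$estimate) - 0.02), 4 * 0.02 * sqrt(2 / 1e5))

  expect_error(sample_loghr_estimate(-1, 100), "true_hr")
  expect_error(sample_loghr_estimate(1, 0), "events")
})

test_that("closed-form success probabilities reproduce the boundary algebra", {
  eff <- tte_design(interim_rule = "efficacy")
  expect_equal(analytic_success_probability(eff, 1), 1 - 0.9^2,
               tolerance = 1e-4)

  eff95 <- tte_design(interim_rule = "efficacy", efficacy_threshold = 0.95,
                      final_threshold = 0.95)
  expect_equal(analytic_success_probability(eff95, 1), 1 - 0.95^2,
               tolerance = 1e-4)

  none <- tte_design(interim_rule = "none")
  expect_equal(analytic_success_probability(none, 1), 0.10,
               tolerance = 1e-4)

  # Monotone non-increasing in the true hazard ratio.
  for (rule in c("none", "futility", "efficacy")) {
    d <- tte_design(interim_rule = rule)
    p <- vapply(c(0.7, 0.8, 0.9, 1), analytic_success_probability,
                numeric(1), design = d)
    expect_true(all(diff(p) <= 0))
  }

  d_corr <- tte_design(interim_rule = "efficacy",
                       look_dependence = "correlated")
  expect_error(analytic_success_probability(d_corr, 1), "correlated")
})

test_that("simulated success matches the closed form for independent looks", {
  n <- 1e5
  for (rule in c("none", "futility", "efficacy")) {
    d <- tte_design(interim_rule = rule)
    for (hr in c(1, 0.9, 0.8, 0.7)) {
      p_hat <- mean(simulate(d, nsim = n, seed = 99, true_hr = hr)$success)
      p <- analytic_success_probability(d, hr)
      expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
    }
  }
})

test_that("trial results respect the decision rules", {
  d <- tte_design(interim_rule = "efficacy")
  res <- simulate(d, nsim = 5000, seed = 2, true_hr = 0.8)
  # Success only through efficacy stop or final analysis.
  expect_true(all(res$stop_reason[res$success] %in% c("efficacy", "final")))
  # Futility stops are never successful; efficacy stops always are.
  expect_true(all(res$success[res$stop_reason == "efficacy"]))
  expect_equal(res$events_at_stop[res$stopped_early],
               rep(100, sum(res$stopped_early)))
  expect_equal(res$events_at_stop[!res$stopped_early],
               rep(200, sum(!res$stopped_early)))

  df <- simulate(tte_design(interim_rule = "futility"), nsim = 5000,
                 seed = 2, true_hr = 1)
  expect_false(any(df$success[df$stop_reason == "futility"]))

  # Determinism: identical seed, identical results.
  expect_identical(res, simulate(d, nsim = 5000, seed = 2, true_hr = 0.8))
  one <- simulate_tte_trial(d, true_hr = 0.8, seed = 11)
  expect_true(is.logical(one$success))
})

test_that("success sets nest path-wise across interim rules under a shared seed", {
  for (mode in c("independent", "correlated")) {
    fut <- tte_design(interim_rule = "futility", look_dependence = mode)
    none <- tte_design(interim_rule = "none", look_dependence = mode)
    eff <- tte_design(interim_rule = "efficacy", look_dependence = mode)
    s_fut <- simulate(fut, nsim = 2e4, seed = 5, true_hr = 0.9)$success
    s_none <- simulate(none, nsim = 2e4, seed = 5, true_hr = 0.9)$success
    s_eff <- simulate(eff, nsim = 2e4, seed = 5, true_hr = 0.9)$success
    # Futility looks only remove successes; efficacy looks only add them.
    expect_true(all(s_none[s_fut]))
    expect_true(all(s_eff[s_none]))
  }
})

test_that("correlated looks share the accumulating score statistic", {
  # The final estimate's marginal law is the same in both modes, so the
  # no-interim design has identical operating characteristics.
  none_ind <- tte_design(interim_rule = "none")
  none_cor <- tte_design(interim_rule = "none",
                         look_dependence = "correlated")
  p_cor <- mean(simulate(none_cor, nsim = 1e5, seed = 8,
                         true_hr = 1)$success)
  expect_lt(abs(p_cor - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))

  # Correlation lowers the efficacy-design type I error relative to
  # independent looks (less fresh noise at the final analysis).
  eff_cor <- tte_design(interim_rule = "efficacy",
                        look_dependence = "correlated")
  p_eff_cor <- mean(simulate(eff_cor, nsim = 1e5, seed = 8,
                             true_hr = 1)$success)
  expect_lt(p_eff_cor, 0.19)
  expect_gt(p_eff_cor, 0.10)
})

test_that("design validation rejects inconsistent settings", {
  expect_error(tte_design(total_events = 100, interim_events = 100),
               "interim_events")
  expect_error(tte_design(efficacy_threshold = 1.2))
  expect_error(tte_design(prior = list(mean = 0)), "prior")
})
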