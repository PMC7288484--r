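# Small designs keep the patient-level tests fast; the accrual rate is set
# so a realistic fraction of enrolled patients lacks follow-up at each look.
small_design <- function(...) {
  binary_design(n_max = 300, schedule = c(100L, 200L),
                efficacy_threshold = 0.99, futility_threshold = 0.10,
                accrual_rate = 1, n_imputations = 100, ...)
}

test_that("even schedules match the printed interim timings", {
  expect_equal(build_even_schedule(1334, 3), c(334L, 667L, 1001L))
  expect_equal(build_even_schedule(1334, 1), 667L)
  expect_identical(build_even_schedule(1334, 0), integer(0))
  # 10 evenly spaced looks of 1334 patients, half-up rounding.
  expect_equal(build_even_schedule(1334, 10),
               as.integer(floor((1:10) * 1334 / 11 + 0.5)))
  expect_error(build_even_schedule(6, 11), "collapses")
})

test_that("trial states validate their count invariants", {
  s <- trial_state(enrolled = c(50, 50), completed = c(40, 40),
                   events = c(18, 12))
  expect_s3_class(s, "trial_state")
  expect_error(trial_state(c(50, 50), c(60, 40), c(1, 1)), "enrol")
  expect_error(trial_state(c(50, 50), c(40, 40), c(41, 0)), "events")
  expect_error(trial_state(c(50, 50), c(-1, 40), c(0, 0)))
})

test_that("P_curr is the success indicator once follow-up is complete", {
  d <- binary_design(n_max = 600, n_interims = 0)
  # Strongly favourable data: superiority probability ~1.
  s_good <- trial_state(c(300, 300), c(300, 300), c(130, 50))
  expect_identical(predictive_prob_success_current(s_good, d), 1)
  # Balanced arms: nowhere near the 0.98 bar.
  s_flat <- trial_state(c(300, 300), c(300, 300), c(130, 130))
  expect_identical(predictive_prob_success_current(s_flat, d), 0)
  expect_error(predictive_prob_success_current(
    trial_state(c(0, 0), c(0, 0), c(0, 0)), d), "enrolled")
})

test_that("P_curr matches the exact beta-binomial enumeration oracle", {
  d <- binary_design(n_max = 700, n_interims = 0)
  n_imp <- 4000
  states <- list(
    trial_state(c(310, 310), c(300, 300), c(130, 98)),   # borderline
    trial_state(c(310, 310), c(300, 300), c(130, 50)),   # clearly in
    trial_state(c(160, 160), c(150, 150), c(66, 48)),
    trial_state(c(50, 50), c(40, 40), c(20, 10))
  )
  for (i in seq_along(states)) {
    st <- states[[i]]
    exact <- oracle_p_curr(st, d)
    set.seed(100 + i)
    mc <- predictive_prob_success_current(st, d, n_imputations = n_imp)
    tol <- 3 * sqrt(max(exact * (1 - exact), 1e-4) / n_imp)
    expect_lt(abs(mc - exact), tol + 1e-12)
  }
})

test_that("P_max extends the imputation to the maximum sample size", {
  d <- binary_design(n_max = 600, n_interims = 0)
  # Already at n_max with complete follow-up: the 0/1 indicator.
  s_done <- trial_state(c(300, 300), c(300, 300), c(130, 50))
  expect_identical(predictive_prob_success_max(s_done, d), 1)
  # Identical large counts per arm: symmetric data cannot plausibly reach
  # the one-sided 0.98 bar at the maximum sample size.
  d9 <- binary_design(n_max = 900, n_interims = 0)
  s_flat <- trial_state(c(430, 430), c(400, 400), c(178, 178))
  set.seed(1)
  expect_lt(predictive_prob_success_max(s_flat, d9, 2000), 0.2)
  # With nothing left to impute, P_max and P_curr coincide by definition.
  expect_identical(predictive_prob_success_max(s_done, d),
                   predictive_prob_success_current(s_done, d))
})

test_that("the trial engine is deterministic and respects its rules", {
  d <- small_design()
  sc <- binary_scenario(0.44, 0.35)
  res <- simulate(d, nsim = 400, seed = 31, scenario = sc)
  expect_identical(res, simulate(d, nsim = 400, seed = 31, scenario = sc))

  expect_true(all(res$success[res$stop_reason == "efficacy"]))
  expect_false(any(res$success[res$stop_reason == "futility"]))
  expect_true(all(res$n_enrolled_at_stop[res$stopped_early] %in%
                    d$schedule))
  expect_equal(unique(res$n_enrolled_at_stop[!res$stopped_early]),
               d$n_max)

  one <- simulate_binary_trial(d, sc, seed = 3)
  expect_true(is.logical(one$success))
})

test_that("degenerate thresholds reduce to the corresponding simpler design", {
  sc <- binary_scenario(0.44, 0.44)
  # Unreachable efficacy bar behaves like the futility-only design.
  d_both <- small_design()
  d_both$efficacy_threshold <- 1
  d_fut <- small_design()
  d_fut$efficacy_threshold <- NULL
  expect_equal(simulate(d_both, nsim = 300, seed = 5, scenario = sc)$success,
               simulate(d_fut, nsim = 300, seed = 5, scenario = sc)$success)

  # Unreachable efficacy and futility bars reproduce the fixed design.
  d_off <- small_design()
  d_off$efficacy_threshold <- 1
  d_off$futility_threshold <- 0
  d_fixed <- binary_design(n_max = 300, n_interims = 0, accrual_rate = 1,
                           n_imputations = 100)
  expect_equal(simulate(d_off, nsim = 300, seed = 5, scenario = sc)$success,
               simulate(d_fixed, nsim = 300, seed = 5,
                        scenario = sc)$success)
})

test_that("stopping rules act path-wise under common random numbers", {
  sc <- binary_scenario(0.44, 0.44)
  n <- 400
  # Futility looks can only remove successes relative to the fixed design.
  d_fut <- small_design()
  d_fut$efficacy_threshold <- NULL
  d_fixed <- binary_design(n_max = 300, n_interims = 0, accrual_rate = 1,
                           n_imputations = 100)
  s_fut <- simulate(d_fut, nsim = n, seed = 17, scenario = sc)$success
  s_fixed <- simulate(d_fixed, nsim = n, seed = 17, scenario = sc)$success
  expect_true(all(s_fixed[s_fut]))

  # Efficacy-only success sets nest as looks are added to a schedule.
  mk_eff <- function(sched) {
    binary_design(n_max = 300, schedule = sched, efficacy_threshold = 0.99,
                  futility_threshold = NULL, accrual_rate = 1,
                  n_imputations = 100)
  }
  s0 <- simulate(mk_eff(150L), nsim = n, seed = 17, scenario = sc)$success
  s1 <- simulate(mk_eff(c(100L, 150L)), nsim = n, seed = 17,
                 scenario = sc)$success
  s2 <- simulate(mk_eff(c(100L, 150L, 200L)), nsim = n, seed = 17,
                 scenario = sc)$success
  expect_true(all(s1[s0]))
  expect_true(all(s2[s1]))
})

test_that("dropout removes patients from numerator and denominator", {
  d <- binary_design(n_max = 300, n_interims = 1, accrual_rate = 1,
                     n_imputations = 100, dropout_rate = 0.03,
                     futility_threshold = NULL)
  res <- simulate(d, nsim = 300, seed = 9,
                  scenario = binary_scenario(0.44, 0.35))
  expect_true(all(res$success %in% c(TRUE, FALSE)))
  # Power with 3% dropout stays in a plausible band for this small trial.
  expect_gt(mean(res$success), 0.2)
})

test_that("design validation enforces the schedule invariants", {
  expect_error(binary_design(n_max = 1333), "even")
  expect_error(binary_design(schedule = c(200, 100)), "increasing")
  expect_error(binary_design(schedule = c(100, 1334)), "n_max")
  expect_error(binary_design(final_threshold = 1), "final_threshold")
  expect_error(binary_scenario(0, 0.4), "p_control")
})
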