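test_that("normal-normal update is the precision-weighted combination", {
  vague <- normal_posterior(0, 1e4)

  # Symmetric zero case: posterior mean stays 0, variance is the harmonic
  # combination v * tau^2 / (v + tau^2), marginally below the data variance.
  p <- update_normal(vague, estimate = 0, estimate_variance = 0.04)
  expect_equal(p$mean, 0)
  expect_equal(p$variance, 0.04 * 1e4 / (0.04 + 1e4), tolerance = 1e-12)

  # Hand-computed precision weighting, cross-checked by numerical Bayes
  # integration on a grid.
  est <- log(0.7); v <- 0.02
  p <- update_normal(vague, est, v)
  expect_equal(p$mean, est * (1 / v) / (1 / v + 1e-4), tolerance = 1e-12)
  grid <- seq(-2, 2, length.out = 40001)
  post <- dnorm(grid, 0, 100) * dnorm(est, grid, sqrt(v))
  post <- post / sum(post)
  expect_equal(p$mean, sum(grid * post), tolerance = 1e-6)
  expect_equal(p$variance, sum((grid - sum(grid * post))^2 * post),
               tolerance = 1e-6)

  expect_error(update_normal(vague, 0, 0), "estimate_variance")
  expect_error(normal_posterior(0, -1), "variance")
})

test_that("normal update limits: vague prior returns the data, infinite data variance returns the prior", {
  est <- 0.3; v <- 0.01
  p <- update_normal(normal_posterior(0, 1e12), est, v)
  expect_equal(p$mean, est, tolerance = 1e-9)
  expect_equal(p$variance, v, tolerance = 1e-9)

  prior <- normal_posterior(-0.2, 0.5)
  p <- update_normal(prior, 5, 1e12)
  expect_equal(p$mean, prior$mean, tolerance = 1e-9)
  expect_equal(p$variance, prior$variance, tolerance = 1e-9)
})

test_that("Pr(HR < 1) is the lower-tail normal probability at zero", {
  expect_equal(prob_hr_below_one(normal_posterior(0, 0.37)), 0.5)
  expect_equal(prob_hr_below_one(normal_posterior(log(0.7), 0.02)),
               pnorm(-log(0.7) / sqrt(0.02)), tolerance = 1e-12)
  expect_equal(prob_hr_below_one(normal_posterior(-10, 0.01)), 1,
               tolerance = 1e-12)

  # Agreement with quadrature of the normal density.
  for (pars in list(c(0.1, 0.3), c(-0.5, 0.02), c(0.02, 1.7))) {
    q <- integrate(dnorm, -Inf, 0, mean = pars[1], sd = sqrt(pars[2]),
                   rel.tol = 1e-12)$value
    expect_equal(prob_hr_below_one(normal_posterior(pars[1], pars[2])), q,
                 tolerance = 1e-10)
  }
})

test_that("beta updates add events and non-events to the shapes", {
  p <- update_beta(beta_posterior(1, 1), 10, 20)
  expect_equal(c(p$alpha, p$beta), c(11, 11))
  p <- update_beta(beta_posterior(1, 1), 0, 0)
  expect_equal(c(p$alpha, p$beta), c(1, 1))
  expect_error(update_beta(beta_posterior(1, 1), 5, 3), "exceed")
  expect_error(update_beta(beta_posterior(1, 1), -1, 3))
  expect_error(beta_posterior(0, 1), "alpha")
})

test_that("superiority probability matches closed forms and quadrature", {
  expect_equal(prob_superiority(beta_posterior(1, 1), beta_posterior(1, 1)),
               0.5, tolerance = 1e-10)
  # Closed form: int 2x (1 - (1-x)^2) dx = 5/6.
  expect_equal(prob_superiority(beta_posterior(2, 1), beta_posterior(1, 2)),
               5 / 6, tolerance = 1e-10)

  set.seed(42)
  for (i in 1:100) {
    ctrl <- beta_posterior(sample(1:400, 1), sample(1:400, 1))
    intv <- beta_posterior(sample(1:400, 1), sample(1:400, 1))
    expect_equal(prob_superiority(ctrl, intv),
                 oracle_prob_superiority(ctrl, intv), tolerance = 1e-8)
    # Complementarity: ties have measure zero.
    expect_equal(prob_superiority(ctrl, intv) +
                   prob_superiority(intv, ctrl), 1, tolerance = 1e-8)
  }

  # Non-integer shapes go through quadrature.
  ctrl <- beta_posterior(2.5, 3.7); intv <- beta_posterior(1.3, 4.1)
  expect_equal(prob_superiority(ctrl, intv),
               oracle_prob_superiority(ctrl, intv), tolerance = 1e-8)
})

test_that("superiority probability is monotone in the intervention event count", {
  ctrl <- beta_posterior(30, 70)
  probs <- vapply(0:40, function(a)
    prob_superiority(ctrl, beta_posterior(1 + a, 100 - a)), numeric(1))
  expect_true(all(diff(probs) <= 1e-12))
})

test_that("predictive event draws follow the beta-binomial", {
  expect_identical(sample_predictive_events(beta_posterior(1, 1), 0, 10),
                   integer(10))
  set.seed(1)
  expect_true(all(sample_predictive_events(beta_posterior(1, 1e9), 100,
                                           200) == 0))
  expect_error(sample_predictive_events(beta_posterior(1, 1), -1))

  # Empirical mean within 3 standard errors of n * alpha / (alpha + beta).
  set.seed(7)
  post <- beta_posterior(3, 5)
  n <- 20
  draws <- sample_predictive_events(post, n, 1e5)
  m <- n * 3 / 8
  # beta-binomial variance: n ab (a+b+n) / ((a+b)^2 (a+b+1))
  v <- n * 3 * 5 * (8 + n) / (8^2 * 9)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 1e5))
  expect_true(all(draws >= 0 & draws <= n))
})
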