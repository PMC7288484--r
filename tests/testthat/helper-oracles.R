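# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: quadrature instead of the finite sum,
# exact enumeration instead of Monte-Carlo imputation.

# Pr(theta_i < theta_c) by numerical integration over the control density.
oracle_prob_superiority <- function(control, intervention) {
  f <- function(x) dbeta(x, control$alpha, control$beta) *
    pbeta(x, intervention$alpha, intervention$beta)
  integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
            subdivisions = 1000L)$value
}

# Beta-binomial pmf: probability of k events among n with a Beta(a, b) rate.
betabinom_pmf <- function(k, n, a, b) {
  exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# Exact P_curr by enumerating every imputed completion of the incomplete
# patients, weighted by the beta-binomial predictive.
oracle_p_curr <- function(state, design) {
  add <- state$enrolled - state$completed
  pc <- design$prior_control
  pi_ <- design$prior_intervention
  ac <- pc$alpha + state$events[1]
  bc <- pc$beta + state$completed[1] - state$events[1]
  ai <- pi_$alpha + state$events[2]
  bi <- pi_$beta + state$completed[2] - state$events[2]
  total <- 0
  for (xc in 0:add[1]) {
    wc <- betabinom_pmf(xc, add[1], ac, bc)
    for (xi in 0:add[2]) {
      wi <- betabinom_pmf(xi, add[2], ai, bi)
      post_c <- beta_posterior(ac + xc,
                               bc + add[1] - xc)
      post_i <- beta_posterior(ai + xi,
                               bi + add[2] - xi)
      ok <- prob_superiority(post_c, post_i) > design$final_threshold
      if (ok) total <- total + wc * wi
    }
  }
  total
}
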