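---
title: "Operating characteristics of Bayesian adaptive two-arm designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operating characteristics of Bayesian adaptive two-arm designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bayesadapt)
```

## The problem

A Bayesian adaptive trial makes interim decisions by comparing posterior (or
posterior-predictive) probabilities of benefit to pre-specified boundaries:
stop early for efficacy if the evidence for benefit is strong, stop early for
futility if success has become implausible. Bayesian *inference* needs no
adjustment for these repeated looks, but the *decision procedure* is still a
sequential test with frequentist operating characteristics: its type I error
(declaring the intervention superior when the arms truly do not differ) grows
with every look that can trigger an efficacy stop, exactly as in a group
sequential design without boundary correction. Regulators generally ask for a
demonstration — usually by simulation — that a confirmatory design controls
type I error at a nominal level such as one-sided 2.5%.

`bayesadapt` simulates two archetypal designs, estimates their operating
characteristics by Monte Carlo, and tunes their stopping boundaries to a
target type I error. Everything is driven by two design constructors; there
is no external data, so the "model object" here is a trial design, and
`simulate()` / `run_oc()` play the roles that `fitted()` and `summary()` play
for a fitted model.

## Design 1: time-to-event endpoint monitored on the log hazard ratio

The monitored quantity is the hazard ratio (HR) between arms, analysed at a
fixed number of events `d`. The estimated log HR at `d` events is treated as
normally distributed around the true log HR with known variance `4/d` — the
standard approximation for 1:1 allocation, in which each event contributes
information 1/4. No patient-level survival times are needed: each simulated
look draws the estimator directly.

With a normal prior N(m, tau^2) on the log HR (default the vague N(0, 10000),
which contributes about as much information as 1/2500 of an event), the
posterior is conjugate normal, and the decision quantity Pr(HR < 1 | data) is
a normal tail probability. The reference design analyses at 200 events with
one optional interim at 100 events:

* **final success**: Pr(HR < 1 | data) > 0.9 at 200 events;
* **futility variant**: stop at 100 events if Pr(HR < 1 | data) < 0.5
  (a probability exactly at 0.5 continues; the tie has probability zero);
* **efficacy variant**: stop at 100 events if Pr(HR < 1 | data) > 0.9, and a
  trial stopped this way counts as successful.

### Dependence between looks

The statistically canonical model of accumulating data makes the final score
statistic the interim score plus an independent increment
(`look_dependence = "correlated"`). The package's default, however, draws the
interim and final estimates *independently* (`"independent"`). The reason is
transparency: under independent looks the efficacy design's null success
probability has the closed form `1 - (1 - p_int)(1 - p_fin)`, which with a
shared threshold `b` at both looks and HR = 1 is exactly `1 - b^2` — 0.19 at
b = 0.9, 0.0975 at b = 0.95. Those are precisely the headline inflation
numbers the simulator reproduces, and
`analytic_success_probability()` provides them as a closed-form oracle
against which every simulated estimate is tested (the closed form retains
the exact prior-shrinkage factor `w = (1/v)/(1/v + 1/tau^2)` rather than its
vague-prior limit, so oracle and simulator agree to machine precision in
distribution, not just asymptotically). Under correlated looks the interim
is less able to add fresh noise at the final analysis, so the same
boundaries inflate the type I error less; both modes are available and
share estimate substreams keyed by look position, so rule variants can be
compared path-wise under a common seed.

```{r cs1}
d_eff <- tte_design(interim_rule = "efficacy")
run_oc(d_eff, scenarios = c(1, 0.9, 0.8, 0.7), n_sims = 1e6, seed = 1)
analytic_success_probability(d_eff, true_hr = 1)  # 0.19
```

## Design 2: binary endpoint with predictive-probability stopping

The second design re-imagines a completed frequentist trial — 1334 patients
randomised 1:1, 44% expected 28-day mortality in the control arm, powered
for a 9 percentage-point absolute reduction — as a Bayesian adaptive design.
Each arm's mortality rate carries an independent Beta(1, 1) prior, updated
by the observed 28-day outcomes. The final analysis declares success when

> Pr(theta_intervention < theta_control | data) > 0.98,

a superiority probability the package computes exactly via the finite-sum
identity for integer beta shapes (quadrature otherwise, 1e-8 absolute
accuracy).

Interim analyses happen at fixed recruitment counts, evenly spaced by
default (`build_even_schedule()`; three looks at 1334 patients fall at 334,
667 and 1001). Because the outcome is observed 28 days after enrolment,
recently recruited patients are incomplete at every look. Two predictive
probabilities drive the decisions:

* `P_curr` — the probability that the trial would succeed *at the current
  sample size* once the incomplete patients' outcomes are known, averaging
  the final success indicator over beta-binomial imputations of those
  outcomes. Stop for efficacy if `P_curr > 0.99`.
* `P_max` — the same probability at the *maximum* sample size, additionally
  imputing all not-yet-enrolled patients. Stop for futility if
  `P_max < 0.10`.

### Choices the trial description leaves open

* **Accrual.** The number of incomplete patients at a look is governed by
  the accrual rate, which is not a reported quantity of the original trial.
  The package makes it an explicit design parameter with a deterministic
  default of 2 patients/day — a realistic multi-centre rate for this
  indication that leaves 56 enrolled patients (28 per arm) without follow-up
  at any interim. Sensitivity to this assumption can be explored directly
  (`accrual_rate`), and the acceptance tolerances for the case-study type I
  errors are wide enough to absorb plausible alternatives.
* **Priors.** "Essentially uniform" arm priors are implemented as
  Beta(1, 1); shapes are configurable, and at several hundred patients per
  arm the difference between reasonable near-uniform choices is negligible.
* **Imputation effort.** `n_imputations` defaults to 500 predictive draws
  per probability; the Monte-Carlo error of `P_curr` near the 0.99 boundary
  is then about 0.004, small against the spacing of trial-to-trial
  variation.
* **Allocation.** Permuted blocks of 2, so every even recruitment count is
  exactly balanced; at odd counts the extra patient's arm is a fair coin
  keyed by block, shared across designs under a common seed.
* **Dropout.** None by default (the 3% figure belongs to the original
  frequentist sample-size calculation); optional uniform missingness
  removes patients from numerator and denominator alike.
* **Ties.** All boundary comparisons are strict, as stated
  (`>` for efficacy and final success, `<` for futility).
* **Rule order.** Where both rules are active at one look, efficacy is
  evaluated first; with the default boundaries both can essentially never
  fire together.

### How the engine evaluates predictive probabilities

A naive implementation calls the superiority probability once per imputation
draw. The engine instead precomputes, for each control event total `s_c` at
the evaluation sample size, the largest intervention event total still
clearing the final bar (a binary search over an exact, monotone function),
memoising these critical counts across trials, imputations and looks. Each
imputation then reduces to two beta-binomial draws and an integer
comparison, which is what makes 10,000 patient-level trials with hundreds of
imputations per look a matter of seconds rather than hours. The two routes
are algebraically identical; the tests cross-check them and compare the
Monte-Carlo `P_curr` against an exact enumeration oracle on small states.

```{r cs2}
redesign <- binary_design(n_interims = 3, futility_threshold = NULL)
run_oc(redesign, n_sims = 1e4, seed = 1)
```

## Operating characteristics, sweeps and common random numbers

`run_oc()` reports the success proportion per scenario (type I error under
the null, power under the target effect) with its Monte-Carlo standard
error `sqrt(p(1-p)/n)`, the mean information at stopping, and early-stop
proportions by reason. `sweep_interims()` rebuilds a design with 0, 1, ...
evenly spaced looks and tabulates how the error rates move: efficacy-only
looks inflate type I error as their number grows, futility-only looks
deflate both type I error and power.

All designs simulated from one master seed share patient-level outcome
streams, and looks at the same recruitment count share imputation streams
(substreams are keyed by seed, stream role and look position). Comparisons
between designs are therefore path-wise wherever the design structures nest:
adding an efficacy look can only add successful trials, adding a futility
look can only remove them, and these statements hold trial-by-trial, not
just in expectation — but only when one schedule's looks are a subset of the
other's. Evenly spaced schedules with different counts interleave rather
than nest, so across such sweeps the monotone trends are statistical, not
path-wise; the tests distinguish the two cases. Common random numbers also
power `compare_schedules()`, whose paired standard error for the effect of
retiming three efficacy looks from 334/667/1001 to 600/900/1100 is an order
of magnitude smaller than the unpaired one.

## Boundary calibration

`calibrate_threshold()` tunes a single stringency scalar to a target type I
error. The simulation stream is drawn once and summarised as per-trial,
per-look posterior probabilities (time-to-event) or `P_curr` values plus the
final success indicator (binary); any candidate threshold is then a pure
filter over that fixed object, so bisection is deterministic given the seed
and candidates differ by no Monte-Carlo noise. For the time-to-event design
the scalar is the shared efficacy/final threshold (recovering 0.95 for a
9.75% target on the efficacy design); for the binary design it is the
`P_curr` efficacy boundary with the final bar held fixed, because `P_curr`
is itself defined in terms of the final bar — retuning that bar would
invalidate the precomputed stream. The search returns the least stringent
admissible threshold; results at the interval edge or with an achieved
error of exactly zero (below the stream's resolution) are flagged
degenerate rather than treated as converged calibrations.

## Problem sizes and what the tests do and do not show

The package's reference runs use 10^6 replications for the time-to-event
design (draws are two normals per trial, so this is cheap) and 10,000
patient-level trials with 400 imputations per look for the binary design.
The test suite exercises the same code paths at smaller sizes — 10^5
time-to-event replications, a few hundred patient-level trials on reduced
designs (n_max 200–300), enumeration-scale imputation states — chosen so
statistical assertions keep 3-standard-error resolution.

The generator emulates the study conditions exactly as stated: direct
normal sampling of the log-HR estimator (no censoring or accrual model for
the survival endpoint — the approximation *is* the model under study), and
for the binary endpoint deterministic accrual, exact Bernoulli outcomes at
fixed true rates, and no covariates, drift, or non-compliance. Passing tests
therefore validate the decision machinery and its operating
characteristics under these idealised conditions; they do not certify
behaviour under informative dropout, time trends in event rates, staggered
site opening, or misspecified follow-up — all of which would need their own
generators.

## Known limitations

* The independent-looks default for the time-to-event design is a
  deliberate modelling convention with a closed form, not the canonical
  accumulating-data process; conclusions about boundary inflation transfer
  qualitatively but the correlated mode gives smaller inflation.
* The binary engine's predictive probabilities are Monte-Carlo quantities;
  boundary decisions within ~2/`n_imputations` of a threshold are subject
  to imputation noise (the enumeration oracle bounds this on small states).
* Calibration tunes one scalar; joint efficacy/futility or per-look
  boundary shapes are out of scope.
* No response-adaptive randomisation, arm dropping, or utility-based
  (decision-theoretic) stopping.
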