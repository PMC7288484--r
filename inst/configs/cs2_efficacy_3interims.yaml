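# Binary-outcome lung-injury trial redesign: 1334 patients (1:1), three
# efficacy-only interims evenly spaced by recruitment (334, 667, 1001),
# stop if P_curr > 0.99, final success if the posterior superiority
# probability exceeds 0.98, uniform Beta(1,1) priors per arm.
endpoint: binary
design:
  n_max: 1334
  n_interims: 3
  efficacy_threshold: 0.99
  final_threshold: 0.98
  prior_control_alpha: 1
  prior_control_beta: 1
  prior_intervention_alpha: 1
  prior_intervention_beta: 1
  accrual_rate: 2
  followup_days: 28
  n_imputations: 500
scenarios:
  - { p_control: 0.44, p_intervention: 0.44, label: "null" }
  - { p_control: 0.44, p_intervention: 0.35, label: "target" }
n_sims: 10000
seed: 20200610
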