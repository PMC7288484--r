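# Time-to-event design with one futility interim at 100 of 200 events:
# continue only if Pr(HR < 1 | data) >= 0.5.
endpoint: tte
design:
  total_events: 200
  interim_events: 100
  interim_rule: futility
  futility_threshold: 0.5
  final_threshold: 0.9
  prior_mean: 0.0
  prior_variance: 10000.0
  look_dependence: independent
scenarios:
  - hr: 1.0
  - hr: 0.9
  - hr: 0.8
  - hr: 0.7
n_sims: 1000000
seed: 20200610
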