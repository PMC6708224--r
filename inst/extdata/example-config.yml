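# Example pipeline configuration for run_pipeline(read_run_config(...)).
seed: 1
k: 3
simulate:
  n_participants: 60
  days: 7
  invalid_day_rate: 0.1
cutpoints:
  sedentary_max: 100
  mvpa_min: 1952
dayparts:
  morning: [6, 12]
  afternoon: [12, 18]
  evening: [18, 24]
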