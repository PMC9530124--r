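# Demo pipeline configuration: a small simulated cohort run end to end.
out_dir: treemort_demo
spec:
  n_subjects: 1200
  n_noise_features: 4
  missingness: 0.05
  seed: 5
horizon: 5y
split_mode: random
n_boot: 100
max_distance_features: 6
tier: all
risk_size: 6
seed: 42
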