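# Demo configuration for run_experiment(): a small mixed-difficulty
# cohort and short sweeps, sized to finish in about a minute.
seed: 1
simulate:
  n_per_class: 300
  n_features: 16
  easy_fraction: 0.6
  ambiguous_fraction: 0.3
  overconfident_wrong_fraction: 0.1
  class_separation: 10
  noise_sd: 1.0
  ocw_shift: 0.75
split:
  train_fraction: 0.7
ensemble:
  k: 5
  hidden: [32, 32]
  epochs: 10
  learning_rate: 0.001
  optimizer: adam
  weight_decay: 0.002
defer:
  hidden: [100, 100]
  epochs: 30
  learning_rate: 0.001
  optimizer: adam
sweeps:
  seeds: [1]
  ldu_alpha: [0.7, 1.2, 2.0]
  ld_alpha: [0.7, 1.2, 2.0]
  dt_threshold: [0.0, 0.3, 0.6]
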