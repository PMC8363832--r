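schema_version: 1
scenario:
  scenario_name: puberty
  design: cohort
  n_waves: 5.0
  sampling: slow
  variability: high
  frame: cohort
  fixed:
    age_c: 0.0
    puberty_c: 2.0
    age_x_puberty: -0.5
  random:
    intercept_sd: 0.5
    slope_sd: 0.0
    residual_sd: 0.5
  mcar_rate: 0.0
  n_replicants: 200.0
  master_seed: 1.0
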