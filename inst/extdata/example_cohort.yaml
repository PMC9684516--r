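# Example deltarad run configuration (desk-scale smoke cohort).
cohort:
  n_patients: 8
  schedules:
    - [80, 40]
    - [70.2, 26]
  grid_shape: [32, 32, 16]
  voxel_spacing_mm: [0.9, 0.9, 2.0]
  n_fiducials: 3
  texture_effect_size: 3.0
  outcome_prevalence: 0.5
  noise_style: sharp
  seed: 7
preprocess:
  quantizer: lloyd_max
  collewet: true
  n_levels: 256
  radius_mm: 5.0
  target_mm: 1.0
model:
  endpoints: [acute_gu, subacute_gu, delta_ipss]
  n_iter: 100
  n_trees: 500
  seed: 8
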