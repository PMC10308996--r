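# Default parameters of the hierarchical bilirubin decision model.
# The shipped values are the published model: edit a copy of this file
# and pass it via --config / read_model_params() to change anything.
alpha_threshold: 0.0125
beta_threshold: 0.0014
comparison_mode: strict
ref_center_nm: 605.0
band_half_width_nm: 5.0
low_model:
  a2: -78.019
  a1: 45.675
  a0: 4.4615
  band_center_nm: 492.0
  r_squared: 0.88
medium_model:
  a2: -79.709
  a1: 88.443
  a0: 7.4801
  band_center_nm: 468.0
  r_squared: 0.92
# no high_model: that cohort had too few participants to calibrate one
synthetic:
  noise_sd: 0.01
  photoisomerization_fraction: 0.15
  source_temperature_K: 3000.0
  coupling:
    deoxy_base: 0.2313687487
    deoxy: 0.012
    met: 0.0142300098
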