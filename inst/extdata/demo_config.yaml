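# Bundled demo configuration: 2 states, 3 Tiger Reserves, 6 Wildlife
# Sanctuaries; each matched PA analysed on a 12 x 12 km synthetic scene
# (24 x 24 pixels at 500 m) over 1984-2012.
seed: 42
pa:
  n_states: 2
  n_tr: 3
  n_wls: 6
scene:
  width: 24
  height: 24
  pixel_size: 500
  years: [1984, 2012]
  obs_per_year: 12
  cloud_fraction: 0.05
  water_fraction: 0.0
  noise_sd: 0.01
thresholds:
  rainfall_window: 500
  wls_min_area: 75
  min_points_per_epoch: 5
  max_insufficient_fraction: 0.20
  robust_min_fraction: 0.20
  substantial_threshold: 15
options:
  declaration_epoch: after
  distance_metric: boundary
  estimator: theil-sen
  timestamp_mode: subset-mean
  epoch_mode: both
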