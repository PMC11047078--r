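# Example pipeline configuration: simulate a dual-reporter recording
# with a 37 -> 32 degC temperature step and analyse it end to end.
#   inst/exec/scnwave all --config example_config.yaml --out runs/example
synth:
  grid_shape: [48, 48]
  n_frames: 240
  frame_interval_h: 1
  baseline_period_h: 23.3
  period_shift_per_epoch_h: [0, 1]
  baseline_slope_per_epoch: [-0.3, 0.8]
  phase_span_h: 8
  n_reporters: 2
  reporter_lag_h: 4
  seed: 42
  temperature_schedule:
    start_h: [0, 120]
    end_h: [120, 240]
    temp_c: [37, 32]
detrend:
  window_h: 24.5
rhythm:
  band_h: [16, 32]
  rae_threshold: 0.3
  transient_skip_h: 12
cluster:
  k: 5
  seed: 7
  n_init: 10
  normalization: zscore
temp_response:
  enabled: true
  transient_skip_h: 0
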