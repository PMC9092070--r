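# Desk-scale demo configuration for `retseg run-all --config demo-config.yaml`
seed: 1
out_dir: retseg_out
pixel_size_um: .na.real
synth:
  n_per_group: 6
  jitter_cv: 0.08
  image_format: png
  width_px: 64
  height_px: 64
  layer_thickness_px:
    RNFL: 8.0
    IPL: 12.0
    INL: 9.0
    OPL: 5.0
  curvature_amplitude_px: 2.0
  curvature_period_px: 60.0
  cell_count: 3
  cell_radius_px: 3.0
  cell_clump_fraction: 0.0
  vacuole_density: 0.5
  noise_sigma: 6.0
  blur_sigma: 0.8
segnet:
  encoder_widths: [8, 8, 16, 16, 16]
  sge_groups: 4
  sge_enabled: true
  convs_per_stage: 1
training:
  epochs: 2
  batch_size: 4
  learning_rate: 0.001
  lr_decay_step: 1
  lr_decay_factor: 0.92
morphometry:
  erosion_iters: 1
  min_layer_area_frac: 0.001
  adherence_ratio: 1.8
  max_split: 6
  source: predicted
stats:
  control_group: control
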