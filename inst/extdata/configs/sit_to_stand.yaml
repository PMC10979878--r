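kind: sit_to_stand
seed: 1
n_trials: 20
helmet:
  n_sensors: 64
  head_radius: 0.09
  standoff: 0.015
sensor_model:
  loop_mode: closed
  sample_rate: 375
  noise_density: 1.5e-14
beamformer:
  band: [13, 30]
  reg_fraction: 0.01
  grid_spacing: 0.004
tfs:
  control_window: [6.5, 7.5]
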