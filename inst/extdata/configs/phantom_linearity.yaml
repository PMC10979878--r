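kind: phantom_linearity
seed: 1
helmet:
  n_sensors: 64
  head_radius: 0.09
  standoff: 0.015
sensor_model:
  sample_rate: 375
  noise_density: 1.5e-14
phantom:
  conditions: [open, closed]
  slot_sensor: 1
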