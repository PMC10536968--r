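system:
  type: double_well
  barrier: 20.0
  period: 360.0
engine:
  timestep: 0.002
  temperature: 300.0
  friction: 2.0
  n_steps: 20000.0
  output_stride: 10.0
gamd:
  cmd_steps: 5000.0
  search_steps: 15000.0
  production_steps: 20000.0
  sigma0: 10.0
leus:
  n_grid: 36.0
  c: 0.005
  le_steps: 50000.0
  us_steps: 50000.0
seed: 1.0
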