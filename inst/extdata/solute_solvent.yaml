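system:
  type: solute_solvent
  n_solute: 4.0
  n_solvent: 20.0
  seed: 1.0
regions:
- name: solute
  terms:
  - 1-1
  - 1-2
  accelerate: yes
- name: solvent
  terms:
  - 2-2
  accelerate: no
engine:
  timestep: 0.002
  temperature: 300.0
  friction: 2.0
  n_steps: 5000.0
  output_stride: 10.0
gamd:
  cmd_steps: 2000.0
  search_steps: 4000.0
  production_steps: 5000.0
  sigma0: 10.0
seed: 1.0
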