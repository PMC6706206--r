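# Tiny 3x3 smoke configuration; completes in seconds.
species: orchestia_gammarellus
regime:
  EY_low: 0.4
  EY_high: 1.0
  sigma_Y: [0.1]
grid:
  p_values: [0.25, 0.5, 0.75]
  q_values: [0.25, 0.5, 0.75]
sim:
  total_steps: 600
  burn_in: 100
  n_cells: 100
  seed: 1
output:
  dir: smoke_out
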