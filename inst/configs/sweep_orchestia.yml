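# Full stochastic sweep for the beach hopper: log lambda_s and pooled mean
# body size over the (p, q) switching-probability grid, at both
# feeding-variability levels.
species: orchestia_gammarellus
regime:
  EY_low: 0.4
  EY_high: 1.0
  sigma_Y: [0.1, 0.5]
grid:
  p_values: [0.0833, 0.1667, 0.25, 0.3333, 0.4167, 0.5, 0.5833, 0.6667, 0.75, 0.8333, 0.9167]
  q_values: [0.0833, 0.1667, 0.25, 0.3333, 0.4167, 0.5, 0.5833, 0.6667, 0.75, 0.8333, 0.9167]
sim:
  total_steps: 3000
  burn_in: 500
  n_cells: 200
  seed: 1
output:
  dir: sweep_orchestia_out
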