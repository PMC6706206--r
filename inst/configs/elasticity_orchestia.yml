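# Dominant-elasticity maps for the beach hopper: per-cell elasticities of
# log lambda_s to the six perturbable traits and the most influential
# trait per (p, q) cell.
species: orchestia_gammarellus
regime:
  EY_low: 0.4
  EY_high: 1.0
  sigma_Y: [0.1, 0.5]
grid:
  p_values: [0.02, 0.26, 0.5, 0.74, 0.98]
  q_values: [0.02, 0.26, 0.5, 0.74, 0.98]
sim:
  total_steps: 3000
  burn_in: 500
  n_cells: 200
  seed: 1
output:
  dir: elasticity_orchestia_out
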