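# Dominant-elasticity maps for the reef manta ray.
species: manta_alfredi
regime:
  EY_low: 0.5
  EY_high: 0.9
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
  dir: elasticity_manta_out
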