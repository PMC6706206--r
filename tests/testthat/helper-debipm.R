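# shared fixtures: presets and a downsized simulation configuration for
# fast unit tests (acceptance tests use the full study settings)

orchestia <- function() species_preset("orchestia_gammarellus")
manta <- function() species_preset("manta_alfredi")

small_config <- function(total_steps = 600, burn_in = 100, n_cells = 100,
                         seed = 1L, ...) {
  sim_config(total_steps = total_steps, burn_in = burn_in,
             n_cells = n_cells, seed = seed, ...)
}

white_noise_orchestia <- function(sigma_Y = 0.1) {
  feeding_regime(0.5, 0.5, 0.4, 1.0, sigma_Y)
}

white_noise_manta <- function(sigma_Y = 0.1) {
  feeding_regime(0.5, 0.5, 0.5, 0.9, sigma_Y)
}
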