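# debipm

Dynamic-energy-budget integral projection models (DEB-IPMs) for
size-structured populations in temporally autocorrelated feeding
environments.

Population ecologists use structured projection models to ask how the
*color* of environmental noise — whether good and bad years come in
runs (red), alternate (blue), or arrive independently (white) — shapes
long-run population growth. Most such analyses perturb statistical
descriptions of vital rates. `debipm` instead builds demography
mechanistically from functional traits: survival, growth, reproduction
and offspring size all follow from a dynamic energy budget driven by
one variable, the expected feeding level `E(Y)`. The package ships
parameterizations for a fast life history (the salt-marsh beach hopper
*Orchestia gammarellus*, monthly timestep) and a slow one (the reef
manta ray *Manta alfredi*, yearly timestep), and is intended for
ecologists studying stochastic demography, noise color, and body size
as a population performance indicator.

## The model

The female body-length distribution `N(L, t)` on the domain Ω is
projected by

    N(L', t+1) = ∫_Ω [ D(L', L) R(L) + G(L', L) S(L) ] N(L, t) dL

with survival `S(L) = exp(-µ)` for `L ≤ L_m E(Y)/κ` (starvation death
above that cutoff), Gaussian growth around the von Bertalanffy mean
`L e^(-rB) + (1 - e^(-rB)) L_m E(Y)` with SD
`(1 - e^(-rB)) L_m σ(Y)`, reproduction
`R(L) = E(Y) R_m L²/L_m²` on the fertile window `[L_p, L_m E(Y)/κ]`,
and parent-independent offspring sizes around `L_b`. The environment
is a two-state Markov chain of good/bad feeding levels with switching
probabilities `p` (good→bad) and `q` (bad→good), autocorrelation
`ρ = 1 - p - q` and good-state frequency `f = q/(p+q)`. Stochastic
projections report the log stochastic growth rate
`log λs = mean of log(N_{t+1}/N_t)` after burn-in and the pooled mean
body size; a perturbation module measures the elasticity of `log λs`
to each of the six measurable life-history traits.

## Worked example

```r
library(debipm)

# deterministic: manta growth rate at a constant feeding level
run_lambda("manta_alfredi", feeding_level = 0.75, sigma_Y = 0.1)
#> manta_alfredi at E(Y) = 0.75, sigma(Y) = 0.1 (200 cells):
#>   lambda = 1.061896 per year
#>   stable mean body size = 298.3668 cm

# stochastic: beach hopper under white noise (p = q = 0.5, f = 1/2)
og  <- species_preset("orchestia_gammarellus")
reg <- feeding_regime(p = 0.5, q = 0.5, EY_low = 0.4, EY_high = 1.0,
                      sigma_Y = 0.1)
project(og, reg, sim_config(seed = 1))
#> <stoch_run> orchestia_gammarellus
#>   log lambda_s = 0.0582 per timestep (tau = 2500)
#>   pooled mean body size = 5.2030

# elasticity of log lambda_s to the puberty length
elasticity(og, reg, sim_config(seed = 1), "L_p")
#> <elasticity_record> L_p: e = -1.4779 (delta = 0.01, base log lambda_s = 0.0582)
```

The deterministic report says a manta population held at `E(Y) = 0.75`
grows ~6%/year with a stable mean disk width near 300 cm. The
stochastic run says a beach-hopper population that sees full feeding
half the months and poor feeding (no reproduction, starvation above
7.8 mm) the other half still grows at ~0.06 log units per month, with
a small pooled mean body length (5.2 mm) because growth is dominated
by newborns. The negative `L_p` elasticity means earlier maturation
(smaller puberty length) raises the stochastic growth rate — the
fast life history is reproduction-limited.

Grid sweeps and dominant-elasticity maps over the `(p, q)` plane are
driven by YAML configs (see `inst/configs/`) either from R
(`run_stochastic_sweep()`, `run_elasticity_sweep()`) or from the shell
wrapper:

```sh
Rscript inst/cli/debipm.R sweep --config inst/configs/smoke_sweep.yml
```

## Package layout

- `R/life_history.R` — trait presets, estimation utilities, allometry,
  staging, YAML import/export of species parameters
- `R/kernel.R` — size mesh, the four fundamental functions, kernel
  assembly, eigen-analysis
- `R/markov_environment.R` — feeding regimes, chain descriptors,
  sequence simulation
- `R/projection.R` — stochastic projection, grid sweeps
- `R/perturbation.R` — elasticities and dominant-trait maps
- `R/synthetic_data.R` — survivorship series, synthetic field samples,
  named regimes
- `R/cli.R` + `inst/cli/debipm.R` — experiment orchestration and shell
  wrapper
- `vignettes/debipm-methods.Rmd` — the model, its assumptions, and the
  numerical choices in detail
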