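test_that("the allocation fraction kappa is refused for perturbation", {
  expect_error(
    elasticity(orchestia(), white_noise_orchestia(), small_config(),
               "kappa"),
    "excluded")
  expect_error(
    elasticity(orchestia(), white_noise_orchestia(), small_config(),
               "offspring_mean"),
    "must be one of")
})

test_that("invariant-violating perturbations are rejected", {
  # doubling L_b pushes it past L_p
  expect_error(
    elasticity(orchestia(), white_noise_orchestia(), small_config(),
               "L_b", delta = 1),
    "L_b < L_p")
})

test_that("raising mortality always lowers the stochastic growth rate", {
  for (reg in list(white_noise_orchestia(),
                   feeding_regime(0.2, 0.7, 0.4, 1.0, 0.1))) {
    rec <- elasticity(orchestia(), reg, small_config(seed = 8), "mu")
    expect_lt(rec$elasticity, 0)
  }
})

test_that("reproduction rate has exactly zero elasticity when nobody matures", {
  # both feeding levels keep the starvation cutoff below the puberty
  # length, so the fertile window is empty and R_m never enters the kernel
  reg <- feeding_regime(0.5, 0.5, 0.30, 0.35, 0.1)
  rec <- elasticity(orchestia(), reg, small_config(seed = 5), "R_m")
  expect_identical(rec$elasticity, 0)
})

test_that("elasticities are insensitive to the perturbation step size", {
  og <- orchestia()
  reg <- white_noise_orchestia()
  cfg <- sim_config(seed = 11)
  states <- simulate_state_sequence(reg, cfg$total_steps, cfg$seed)
  base <- project(og, reg, cfg, states = states)
  pars <- c("L_b", "L_p", "L_m", "R_m", "rB", "mu")
  e_small <- vapply(pars, function(nm) {
    elasticity(og, reg, cfg, nm, delta = 0.005, states = states,
               base_run = base)$elasticity
  }, numeric(1))
  e_std <- vapply(pars, function(nm) {
    elasticity(og, reg, cfg, nm, delta = 0.01, states = states,
               base_run = base)$elasticity
  }, numeric(1))
  expect_identical(sign(e_small), sign(e_std))
  expect_identical(order(-abs(e_small)), order(-abs(e_std)))
})

test_that("forward and central differences agree in sign on a 3x3 grid", {
  og <- orchestia()
  cfg <- sim_config(total_steps = 1500, burn_in = 300, n_cells = 120,
                    seed = 7)
  pars <- c("L_b", "L_p", "L_m", "R_m", "rB", "mu")
  for (p in c(0.2, 0.5, 0.8)) for (q in c(0.2, 0.5, 0.8)) {
    reg <- feeding_regime(p, q, 0.4, 1.0, 0.1)
    states <- simulate_state_sequence(reg, cfg$total_steps, 99)
    base <- project(og, reg, cfg, states = states)
    fw <- vapply(pars, function(nm) {
      elasticity(og, reg, cfg, nm, delta = 0.01, states = states,
                 base_run = base)$elasticity
    }, numeric(1))
    bw <- vapply(pars, function(nm) {
      elasticity(og, reg, cfg, nm, delta = -0.01, states = states,
                 base_run = base)$elasticity
    }, numeric(1))
    central <- (fw + bw) / 2
    # near-zero elasticities carry no stable sign; compare above 1e-4
    sel <- pmax(abs(fw), abs(central)) > 1e-4
    expect_identical(sign(fw[sel]), sign(central[sel]))
  }
})

test_that("base and perturbed runs share the environment sequence", {
  og <- orchestia()
  reg <- white_noise_orchestia()
  cfg <- small_config(seed = 13)
  states <- simulate_state_sequence(reg, cfg$total_steps, cfg$seed)
  rec <- elasticity(og, reg, cfg, "L_m", states = states)
  # manual reconstruction under the same sequence matches exactly
  base <- project(og, reg, cfg, states = states)
  pert_par <- debipm:::perturb_params(og, "L_m", 0.01)
  pert <- project(pert_par, reg, cfg, states = states)
  expect_equal(rec$base_log_lambda_s, base$log_lambda_s)
  expect_equal(rec$elasticity,
               (pert$log_lambda_s - base$log_lambda_s) / log(1.01))
})

test_that("dominant-parameter maps record per-cell winners and descriptors", {
  m <- dominant_parameter_map(orchestia(), white_noise_orchestia(),
                              c(0.3, 0.7), c(0.3, 0.7),
                              small_config(seed = 3))
  expect_equal(nrow(m), 4L)
  expect_equal(m$rho, 1 - m$p - m$q)
  expect_true(all(m$dominant %in% c("L_b", "L_p", "L_m", "R_m", "rB", "mu")))
  e_cols <- paste0("e_", c("L_b", "L_p", "L_m", "R_m", "rB", "mu"))
  expect_true(all(e_cols %in% names(m)))
  for (i in seq_len(nrow(m))) {
    e <- unlist(m[i, e_cols])
    expect_equal(paste0("e_", m$dominant[i]), names(e)[which.max(abs(e))])
  }
  m2 <- dominant_parameter_map(orchestia(), white_noise_orchestia(),
                               c(0.3, 0.7), c(0.3, 0.7),
                               small_config(seed = 3))
  expect_identical(m, m2)
})

test_that("elasticity grids reshape to long format without loss", {
  m <- dominant_parameter_map(orchestia(), white_noise_orchestia(),
                              0.5, c(0.3, 0.7), small_config(seed = 2))
  long <- elasticity_long(m)
  expect_equal(nrow(long), 2L * 6L)
  sub <- long[long$parameter == "L_p", ]
  expect_equal(sub$elasticity, m$e_L_p)
})
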