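test_that("mesh spans the starvation cutoff and pads by five growth SDs", {
  m <- build_mesh(orchestia(), 0.1, 200)
  expect_equal(m$upper, 15.61 / 0.8)  # 19.5125 mm
  expect_equal(m$lower, 2.83853483833, tolerance = 1e-9)
  expect_equal(build_mesh(manta(), 0.1, 200)$upper, 550 / 0.8)  # 687.5 cm
  expect_equal(m$midpoints,
               m$lower + (seq_len(200) - 0.5) * m$cell_width)
  expect_true(all(diff(m$midpoints) > 0))
  expect_error(build_mesh(orchestia(), 0.1, 1), "n_cells")
})

test_that("survival is e^-mu below the starvation cutoff and zero above", {
  og <- orchestia()
  expect_equal(survival_probability(10, og, 1), exp(-0.27))
  expect_equal(survival_probability(10, og, 0.4), 0)  # cutoff 7.805 mm
  cutoff <- og$L_m * 0.6 / og$kappa
  expect_equal(survival_probability(cutoff, og, 0.6), exp(-og$mu))
  expect_equal(survival_probability(cutoff + 1e-9, og, 0.6), 0)
  # an individual of maximum length starves whenever E(Y) < kappa
  expect_equal(survival_probability(og$L_m, og, 0.79), 0)
  expect_error(survival_probability(10, og, 1.2), "feeding_level")
  expect_error(survival_probability(-1, og, 1), "L must")
})

test_that("expected growth follows the von Bertalanffy curve", {
  og <- orchestia()
  expect_equal(growth_mean(og$L_m, og, 1), og$L_m)  # fixed point
  expect_equal(growth_mean(130, manta(), 1), 199.186511207, tolerance = 1e-9)
  # above the ultimate length individuals shrink toward L_inf = L_m E(Y)
  L_inf <- og$L_m * 0.5
  expect_lt(growth_mean(L_inf + 2, og, 0.5), L_inf + 2)
  expect_gt(growth_mean(L_inf - 2, og, 0.5), L_inf - 2)
})

test_that("growth SD scales linearly in sigma(Y) and is length-free", {
  og <- orchestia()
  expect_equal(growth_sd(og, 0.1), 0.190293032333, tolerance = 1e-9)
  expect_equal(growth_sd(og, 0), 0)
  expect_equal(growth_sd(og, 0.5), 5 * growth_sd(og, 0.1))
  expect_error(growth_sd(og, -0.1), "sigma_Y")
})

test_that("growth transition columns are probability distributions", {
  og <- orchestia()
  mesh <- build_mesh(og, 0.1, 150)
  G <- growth_transition(mesh, og, 1, 0.1)
  expect_true(all(G >= 0))
  sums <- colSums(G)
  interior <- mesh$midpoints > mesh$lower + 1 & mesh$midpoints < mesh$upper - 1
  expect_true(all(sums[interior] >= 0.999 & sums[interior] <= 1 + 1e-12))

  # zero-noise limit: all mass in the cell containing the deterministic mean
  G0 <- growth_transition(mesh, og, 1, 0)
  expect_true(all(colSums(G0 > 0) == 1))
  j <- 40
  k <- findInterval(growth_mean(mesh$midpoints[j], og, 1), mesh$edges)
  expect_equal(G0[k, j], 1)
})

test_that("the no-shrink policy keeps individuals at or above their size", {
  ma <- manta()
  mesh <- build_mesh(ma, 0.1, 150)
  G <- growth_transition(mesh, ma, 0.5, 0.1)
  expect_true(all(G[upper.tri(G)] == 0))  # no mass below the source cell
  # a source above L_inf = 275 cm neither shrinks nor drifts upward
  j <- which.min(abs(mesh$midpoints - 320))
  expect_equal(G[j, j], 1)
  expect_equal(sum(G[, j]), 1)
  # a growing source keeps its full mass (shrink tail lumped at source)
  j2 <- which.min(abs(mesh$midpoints - 150))
  expect_equal(sum(G[, j2]), 1, tolerance = 1e-9)
  expect_gt(sum(G[(j2 + 1):nrow(G), j2]), 0.9)
})

test_that("a mesh/sigma mismatch triggers the eviction warning", {
  og <- orchestia()
  mesh <- build_mesh(og, 0.05, 100)  # padding sized for small noise
  expect_warning(growth_transition(mesh, og, 1, 3), "eviction")
  expect_silent(growth_transition(mesh, og, 1, 0.05))
})

test_that("reproduction is fertile only between puberty and starvation", {
  og <- orchestia()
  expect_equal(reproduction_rate(5, og, 1), 0)           # juvenile
  expect_equal(reproduction_rate(og$L_m, og, 1), og$R_m) # max rate
  expect_equal(reproduction_rate(7.3, og, 1), 6.99825708401,
               tolerance = 1e-9)
  # at E(Y) = 0.4 the cutoff is 7.805 mm: 7.3 is fertile, scaled by E(Y)
  expect_equal(reproduction_rate(7.3, og, 0.4), 0.4 * 32 * 7.3^2 / 15.61^2)
  expect_equal(reproduction_rate(10, og, 0.4), 0)   # starved at 0.4
  expect_error(reproduction_rate(7.3, og, -0.1), "feeding_level")
})

test_that("offspring distribution is a unit-mass vector around L_b", {
  og <- orchestia()
  mesh <- build_mesh(og, 0.1, 200)
  d <- offspring_distribution(mesh, og)
  expect_equal(sum(d), 1)
  window <- abs(mesh$midpoints - og$L_b) <= 3 * sqrt(og$offspring_variance) +
    mesh$cell_width
  expect_gt(sum(d[window]), 0.99)

  ma <- manta()
  mm <- build_mesh(ma, 0.1, 200)
  dm <- offspring_distribution(mm, ma)  # zero variance: point mass
  expect_equal(sum(dm > 0), 1L)
  expect_equal(mm$midpoints[which(dm > 0)], 130, tolerance = mm$cell_width)
})

test_that("assembled kernels are nonnegative with zero starved columns", {
  og <- orchestia()
  mesh <- build_mesh(og, 0.1, 200)
  k <- assemble_kernel(mesh, og, 0.4, 0.1)
  expect_true(all(k$matrix >= 0))
  cutoff <- og$L_m * 0.4 / og$kappa
  starved <- mesh$edges[-(mesh$n_cells + 1)] > cutoff
  expect_true(all(k$matrix[, starved] == 0))

  # juvenile, non-starved columns sum to e^-mu within eviction tolerance
  k1 <- assemble_kernel(mesh, og, 1, 0.1)
  juv <- mesh$midpoints > og$L_b & mesh$midpoints < og$L_p - mesh$cell_width
  expect_equal(colSums(k1$matrix)[juv], rep(exp(-og$mu), sum(juv)),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("power iteration matches a dense eigendecomposition", {
  og <- orchestia()
  for (sp in list(orchestia(), manta())) {
    mesh <- build_mesh(sp, 0.1, 10)
    k <- assemble_kernel(mesh, sp, 0.9, 0.1)
    pi_est <- dominant_eigenpair(k)
    dense <- eigen(k$matrix)
    expect_equal(pi_est$lambda, max(Re(dense$values)), tolerance = 1e-8)
  }
  # eigenvalue homogeneity under scaling
  mesh <- build_mesh(og, 0.1, 60)
  A <- assemble_kernel(mesh, og, 0.8, 0.1)$matrix
  expect_equal(dominant_eigenpair(3 * A)$lambda,
               3 * dominant_eigenpair(A)$lambda, tolerance = 1e-8)
  expect_error(dominant_eigenpair(matrix(c(1, -1, 0, 1), 2)), "nonnegative")
})

test_that("lambda is nondecreasing in feeding level for both presets", {
  levels <- seq(0.4, 1.0, by = 0.05)
  for (sp in list(orchestia(), manta())) {
    mesh <- build_mesh(sp, 0.1, 200)
    lam <- vapply(levels, function(y) {
      dominant_eigenpair(assemble_kernel(mesh, sp, y, 0.1))$lambda
    }, numeric(1))
    # iterative lambda estimates carry O(tol / spectral gap) error, so
    # allow a tiny numerical wobble on the survival-only plateau
    expect_true(all(diff(lam) >= -1e-6))
  }
})

test_that("a sterile population declines at exactly the mortality rate", {
  # R_m = 0: the dominant eigenvalue must equal e^-mu
  og <- orchestia()
  sterile <- deb_params(L_b = og$L_b, L_p = og$L_p, L_m = og$L_m, R_m = 0,
                        rB = og$rB, mu = og$mu, kappa = og$kappa,
                        offspring_mean = og$offspring_mean,
                        offspring_variance = og$offspring_variance)
  mesh <- build_mesh(sterile, 0.1, 200)
  for (y in c(0.75, 1.0)) {
    lam <- dominant_eigenpair(assemble_kernel(mesh, sterile, y, 0.1))$lambda
    expect_equal(lam, exp(-og$mu), tolerance = 1e-6)
  }
})

test_that("mean body size averages midpoints by weight", {
  og <- orchestia()
  mesh <- build_mesh(og, 0.1, 100)
  w <- numeric(100); w[7] <- 1
  expect_equal(mean_body_size(w, mesh), mesh$midpoints[7])
  w2 <- numeric(100); w2[c(10, 20)] <- 0.5
  expect_equal(mean_body_size(w2, mesh),
               mean(mesh$midpoints[c(10, 20)]))
  eig <- dominant_eigenpair(assemble_kernel(mesh, og, 1, 0.1))
  ms <- mean_body_size(eig$stable_distribution, mesh)
  expect_gt(ms, og$L_b)
  expect_lt(ms, og$L_m / og$kappa)
  expect_error(mean_body_size(numeric(100), mesh), "no mass")
})

test_that("kernels export with a structured sidecar", {
  path <- withr::local_tempfile(fileext = ".tsv")
  og <- orchestia()
  mesh <- build_mesh(og, 0.1, 30)
  k <- assemble_kernel(mesh, og, 0.8, 0.1)
  write_kernel(k, path)
  mat <- as.matrix(read.delim(path, header = FALSE))
  expect_equal(unname(mat), unname(k$matrix), tolerance = 1e-12)
  side <- yaml::read_yaml(paste0(path, ".yml"))
  expect_equal(side$feeding_level, 0.8)
  expect_equal(side$mesh$n_cells, 30)
  expect_equal(side$params$L_m, 15.61)
})
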