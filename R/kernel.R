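# DEB-IPM projection kernel: size mesh, the four fundamental functions
# (survival, growth, reproduction, parent-offspring), their cell-integrated
# discretization, and deterministic eigen-analysis.

#' Discretize the body-length domain
#'
#' Builds a regular mesh of \code{n_cells} cells spanning every reachable
#' size: the lower bound is the birth size minus five growth standard
#' deviations (floored at zero), the upper bound the larger of the
#' full-feeding starvation cutoff \code{L_m / kappa} and
#' \code{L_m + 5 sd}. Five-standard-deviation padding keeps eviction
#' (probability mass leaking off the mesh) negligible for interior sizes.
#'
#' @param params A [deb_params()] object.
#' @param sigma_Y Feeding-level standard deviation used to size the
#'   padding via the growth standard deviation ([growth_sd()]).
#' @param n_cells Number of mesh cells (>= 2; >= 50 recommended, default
#'   200).
#' @return An object of class \code{size_mesh} with fields \code{lower},
#'   \code{upper}, \code{n_cells}, \code{edges}, \code{midpoints},
#'   \code{cell_width}.
#' @export
build_mesh <- function(params, sigma_Y, n_cells = 200) {
  stopifnot(inherits(params, "deb_params"))
  if (!is.numeric(n_cells) || n_cells < 2) {
    stop("n_cells must be at least 2", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  sg <- growth_sd(params, sigma_Y)
  lower <- max(0, params$L_b - 5 * sg)
  upper <- max(params$L_m / params$kappa, params$L_m + 5 * sg)
  edges <- seq(lower, upper, length.out = n_cells + 1L)
  cell_width <- (upper - lower) / n_cells
  structure(
    list(lower = lower, upper = upper, n_cells = n_cells,
         edges = edges,
         midpoints = edges[-(n_cells + 1L)] + cell_width / 2,
         cell_width = cell_width),
    class = "size_mesh"
  )
}

#' @export
print.size_mesh <- function(x, ...) {
  cat(sprintf("<size_mesh> %d cells on [%g, %g], width %g\n",
              x$n_cells, x$lower, x$upper, x$cell_width))
  invisible(x)
}

check_feeding_level <- function(feeding_level) {
  if (!is.numeric(feeding_level) || length(feeding_level) != 1L ||
      feeding_level < 0 || feeding_level > 1) {
    stop("feeding_level E(Y) must be a single value in [0, 1]", call. = FALSE)
  }
  feeding_level
}

#' Survival probability at length L
#'
#' Individuals survive one timestep with probability \code{exp(-mu)}
#' unless maintenance exceeds assimilated energy, which happens at
#' lengths above the starvation cutoff \code{L_m * E(Y) / kappa}; there
#' survival is zero (an individual of size \code{L_m} starves whenever
#' \code{E(Y) < kappa}).
#'
#' @param L Body length(s), > 0; vectorized.
#' @param params A [deb_params()] object.
#' @param feeding_level Expected feeding level E(Y) in \code{[0, 1]}.
#' @return Survival probability in \code{[0, 1]}.
#' @export
survival_probability <- function(L, params, feeding_level) {
  stopifnot(inherits(params, "deb_params"))
  check_feeding_level(feeding_level)
  if (!is.numeric(L) || any(L <= 0)) stop("L must be > 0", call. = FALSE)
  cutoff <- params$L_m * feeding_level / params$kappa
  ifelse(L <= cutoff, exp(-params$mu), 0)
}

#' Expected length after one timestep (von Bertalanffy mean)
#'
#' \code{E[L'] = L exp(-rB) + (1 - exp(-rB)) * L_m * E(Y)}: lengths decay
#' exponentially toward the feeding-level-dependent ultimate length
#' \code{L_inf = L_m * E(Y)}; individuals above \code{L_inf} shrink
#' toward it (whether realized shrinkage is allowed is a kernel-level
#' policy, see [growth_transition()]).
#'
#' @inheritParams survival_probability
#' @return Expected length at the next timestep.
#' @export
growth_mean <- function(L, params, feeding_level) {
  stopifnot(inherits(params, "deb_params"))
  check_feeding_level(feeding_level)
  if (!is.numeric(L) || any(L <= 0)) stop("L must be > 0", call. = FALSE)
  d <- exp(-params$rB)
  L * d + (1 - d) * params$L_m * feeding_level
}

#' Growth standard deviation
#'
#' \code{sd = (1 - exp(-rB)) * L_m * sigma_Y}, independent of current
#' length and of E(Y): variability in feeding level propagates into the
#' spread of realized growth.
#'
#' @param params A [deb_params()] object.
#' @param sigma_Y Feeding-level standard deviation (>= 0).
#' @return Length standard deviation of the one-step growth increment.
#' @export
growth_sd <- function(params, sigma_Y) {
  stopifnot(inherits(params, "deb_params"))
  if (!is.numeric(sigma_Y) || length(sigma_Y) != 1L || sigma_Y < 0) {
    stop("sigma_Y must be a single nonnegative number", call. = FALSE)
  }
  (1 - exp(-params$rB)) * params$L_m * sigma_Y
}

#' Cell-to-cell growth transition matrix
#'
#' Column j holds, for source midpoint \code{L_j}, a Gaussian with mean
#' [growth_mean()] and standard deviation [growth_sd()], integrated over
#' each destination cell (difference of the normal CDF at the cell
#' edges). Cell integration (rather than a midpoint density rule) is
#' required because the offspring and zero-noise kernels can be far
#' narrower than one cell; it degrades gracefully to point masses.
#'
#' When shrinking is forbidden, shrinkage outcomes are mapped to "stay
#' at the current size": a source whose expected growth increment is
#' non-positive (length at or above the ultimate length
#' \code{L_m * E(Y)}) keeps all its mass in its own cell, and for a
#' growing source the sub-source (shrinkage) tail is lumped into the
#' source cell while the genuine growth mass above it is kept as is.
#' This preserves column mass exactly and keeps a non-growing
#' individual at its length instead of forcing a spurious upward drift
#' across the starvation cutoff, which a
#' truncate-below-and-renormalize rule would do.
#'
#' A warning fires if any interior source column loses more than 1% of
#' its mass off the mesh (eviction guard).
#'
#' @param mesh A [build_mesh()] object.
#' @param params A [deb_params()] object.
#' @param feeding_level Expected feeding level E(Y).
#' @param sigma_Y Feeding-level standard deviation.
#' @param shrink_allowed Override of the preset's shrink policy.
#' @return An \code{n_cells x n_cells} matrix; columns of interior
#'   sources sum to 1 within eviction tolerance.
#' @export
growth_transition <- function(mesh, params, feeding_level, sigma_Y,
                              shrink_allowed = params$shrink_allowed) {
  stopifnot(inherits(mesh, "size_mesh"), inherits(params, "deb_params"))
  check_feeding_level(feeding_level)
  n <- mesh$n_cells
  means <- growth_mean(mesh$midpoints, params, feeding_level)
  sd <- growth_sd(params, sigma_Y)

  if (sd == 0) {
    # degenerate: all mass in the cell containing the deterministic mean
    G <- matrix(0, n, n)
    k <- findInterval(means, mesh$edges, rightmost.closed = TRUE)
    ok <- k >= 1L & k <= n
    G[cbind(k[ok], which(ok))] <- 1
  } else {
    cdf <- outer(mesh$edges, means, function(e, m) stats::pnorm((e - m) / sd))
    G <- cdf[-1L, , drop = FALSE] - cdf[-(n + 1L), , drop = FALSE]
    # eviction guard: sources in the central half of the mesh must keep
    # their mass; losses there indicate a mesh/sigma mismatch (the mesh
    # padding is sized for a different growth SD than the one in use)
    span <- mesh$upper - mesh$lower
    central <- mesh$midpoints > mesh$lower + span / 4 &
      mesh$midpoints < mesh$upper - span / 4
    lost <- central & colSums(G) < 0.99
    if (any(lost)) {
      warning(sprintf("%d interior growth column(s) lose > 1%% mass to eviction",
                      sum(lost)), call. = FALSE)
    }
  }

  if (!shrink_allowed) {
    frozen <- means <= mesh$midpoints
    for (j in seq_len(n)) {
      if (frozen[j]) {
        G[, j] <- 0
        G[j, j] <- 1
      } else if (j > 1L) {
        below <- sum(G[seq_len(j - 1L), j])
        G[seq_len(j - 1L), j] <- 0
        G[j, j] <- G[j, j] + below
      }
    }
  }
  G
}

#' Reproduction rate at length L
#'
#' Offspring produced per timestep by an individual of length L:
#' zero below the puberty length \code{L_p} and above the starvation
#' cutoff \code{L_m * E(Y) / kappa}; otherwise
#' \code{E(Y) * R_m * L^2 / L_m^2}, so an individual of maximum length
#' at full feeding reproduces at the maximum rate \code{R_m}.
#'
#' @inheritParams survival_probability
#' @return Offspring per timestep (nonnegative).
#' @export
reproduction_rate <- function(L, params, feeding_level) {
  stopifnot(inherits(params, "deb_params"))
  check_feeding_level(feeding_level)
  if (!is.numeric(L) || any(L <= 0)) stop("L must be > 0", call. = FALSE)
  cutoff <- params$L_m * feeding_level / params$kappa
  ifelse(L >= params$L_p & L <= cutoff,
         feeding_level * params$R_m * L^2 / params$L_m^2,
         0)
}

#' Offspring size distribution over mesh cells
#'
#' Parent-independent probability vector of offspring lengths: a normal
#' with mean \code{offspring_mean} (= L_b) and variance
#' \code{offspring_variance}, cell-integrated and renormalized to sum
#' exactly 1. Zero variance yields a point mass on the cell containing
#' the birth length.
#'
#' @param mesh A [build_mesh()] object.
#' @param params A [deb_params()] object.
#' @return Probability vector of length \code{mesh$n_cells}.
#' @export
offspring_distribution <- function(mesh, params) {
  stopifnot(inherits(mesh, "size_mesh"), inherits(params, "deb_params"))
  n <- mesh$n_cells
  if (params$offspring_variance == 0) {
    d <- numeric(n)
    k <- findInterval(params$offspring_mean, mesh$edges, rightmost.closed = TRUE)
    if (k < 1L || k > n) {
      stop("offspring_mean falls outside the mesh", call. = FALSE)
    }
    d[k] <- 1
    return(d)
  }
  sd <- sqrt(params$offspring_variance)
  d <- diff(stats::pnorm((mesh$edges - params$offspring_mean) / sd))
  s <- sum(d)
  if (s <= 0) stop("offspring distribution has no mass on the mesh", call. = FALSE)
  d / s
}

#' Assemble the DEB-IPM projection kernel for one feeding level
#'
#' Discretized projection operator
#' \code{A[i, j] = G[i, j] * S_j + R_j * D[i]}: the growth term is
#' conditional on survival, while offspring are produced within the
#' timestep before mortality acts. Only non-starving adults reproduce:
#' the fertile window of the reproduction function closes at the
#' starvation cutoff, so columns for fully starved source cells
#' (\code{L > L_m * E(Y) / kappa}) are identically zero.
#'
#' The survival and reproduction functions are discontinuous (at the
#' starvation cutoff and at the puberty length), so \code{S_j} and
#' \code{R_j} are their exact averages over cell j rather than point
#' evaluations at the midpoint. Midpoint sampling would make the kernel
#' a step function of \code{L_p} and \code{L_m}: a 1\% perturbation
#' that crosses no midpoint would then have exactly zero effect,
#' corrupting elasticity analysis. Cell averaging restores smooth
#' parameter dependence.
#'
#' @param mesh A [build_mesh()] object.
#' @param params A [deb_params()] object.
#' @param feeding_level Expected feeding level E(Y).
#' @param sigma_Y Feeding-level standard deviation.
#' @param shrink_allowed Override of the preset's shrink policy.
#' @return An object of class \code{deb_kernel} with fields
#'   \code{matrix}, \code{feeding_level}, \code{sigma_Y}, \code{mesh},
#'   \code{params}.
#' @export
assemble_kernel <- function(mesh, params, feeding_level, sigma_Y,
                            shrink_allowed = params$shrink_allowed) {
  check_feeding_level(feeding_level)
  n <- mesh$n_cells
  a <- mesh$edges[-(n + 1L)]
  b <- mesh$edges[-1L]
  h <- mesh$cell_width
  cutoff <- params$L_m * feeding_level / params$kappa

  # cell-averaged survival: e^-mu on the non-starved part of each cell
  S <- exp(-params$mu) * pmax(0, pmin(b, cutoff) - a) / h

  # cell-averaged reproduction: E(Y) R_m L^2 / L_m^2 integrated over the
  # fertile overlap [L_p, cutoff] of each cell
  lo <- pmax(a, params$L_p)
  hi <- pmin(b, cutoff)
  R <- ifelse(hi > lo,
              feeding_level * params$R_m / params$L_m^2 *
                (hi^3 - lo^3) / (3 * h),
              0)

  G <- growth_transition(mesh, params, feeding_level, sigma_Y, shrink_allowed)
  D <- offspring_distribution(mesh, params)
  A <- sweep(G, 2L, S, `*`) + outer(D, R)
  structure(
    list(matrix = A, feeding_level = feeding_level, sigma_Y = sigma_Y,
         mesh = mesh, params = params),
    class = "deb_kernel"
  )
}

#' @export
print.deb_kernel <- function(x, ...) {
  cat(sprintf("<deb_kernel> %d x %d at E(Y) = %g, sigma(Y) = %g\n",
              x$mesh$n_cells, x$mesh$n_cells, x$feeding_level, x$sigma_Y))
  invisible(x)
}

kernel_matrix <- function(kernel) {
  if (inherits(kernel, "deb_kernel")) kernel$matrix else as.matrix(kernel)
}

#' Dominant eigenvalue and stable size distribution
#'
#' Power iteration on the nonnegative projection kernel: the dominant
#' eigenvalue is the asymptotic per-timestep growth factor lambda and
#' the normalized right eigenvector the stable body-size distribution.
#' Iteration stops when successive lambda estimates differ by less than
#' \code{tol}.
#'
#' When the two leading eigenvalues are nearly degenerate (which happens
#' near feeding levels where the fertile window opens through the tail
#' of the growth kernel only), power iteration mixes too slowly to reach
#' \code{tol} within the cap; the function then falls back to a dense
#' eigendecomposition, which is exact and cheap at the default mesh
#' resolution. The \code{method} field records which path produced the
#' result.
#'
#' @param kernel A [assemble_kernel()] object or a plain nonnegative
#'   matrix.
#' @param tol Convergence tolerance on lambda (default 1e-10).
#' @param max_iter Iteration cap before the dense fallback (default
#'   10000).
#' @return List with \code{lambda}, \code{stable_distribution}
#'   (sums to 1), \code{iterations} (NA for the dense path), and
#'   \code{method} ("power" or "dense").
#' @export
dominant_eigenpair <- function(kernel, tol = 1e-10, max_iter = 10000) {
  A <- kernel_matrix(kernel)
  if (any(A < 0)) stop("kernel must be nonnegative", call. = FALSE)
  n <- nrow(A)
  v <- rep(1 / n, n)
  lambda_old <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- A %*% v
    lambda <- sum(w)  # v sums to 1, so sum(Av)/sum(v) = sum(w)
    if (lambda <= 0) {
      stop("kernel annihilates the population vector (all-starved regime?)",
           call. = FALSE)
    }
    v <- as.vector(w) / lambda
    if (!is.na(lambda_old) && abs(lambda - lambda_old) < tol) {
      return(list(lambda = lambda, stable_distribution = v, iterations = it,
                  method = "power"))
    }
    lambda_old <- lambda
  }
  # near-degenerate spectrum: solve densely instead
  es <- eigen(A)
  k <- which.max(Re(es$values))
  vec <- abs(Re(es$vectors[, k]))
  list(lambda = Re(es$values[k]), stable_distribution = vec / sum(vec),
       iterations = NA_integer_, method = "dense")
}

#' Mean body size of a distribution over mesh cells
#'
#' @param distribution Nonnegative weight vector over cells
#'   (renormalized internally).
#' @param mesh The matching [build_mesh()] object.
#' @return Weighted mean of the cell midpoints.
#' @export
mean_body_size <- function(distribution, mesh) {
  stopifnot(inherits(mesh, "size_mesh"))
  s <- sum(distribution)
  if (!is.finite(s) || s <= 0) {
    stop("distribution has no mass", call. = FALSE)
  }
  sum(mesh$midpoints * distribution) / s
}

#' Export a kernel as a delimited matrix with a structured sidecar
#'
#' Writes the kernel matrix as a tab-separated file and a YAML sidecar
#' (\code{<path>.yml}) recording the parameters, feeding level and mesh,
#' for external inspection.
#'
#' @param kernel A [assemble_kernel()] object.
#' @param path Output path for the matrix.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "deb_kernel"))
  utils::write.table(kernel$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- list(
    feeding_level = kernel$feeding_level,
    sigma_Y = kernel$sigma_Y,
    mesh = list(lower = kernel$mesh$lower, upper = kernel$mesh$upper,
                n_cells = kernel$mesh$n_cells),
    params = unclass(kernel$params)
  )
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}
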