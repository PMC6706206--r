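# Numerical elasticity of log lambda_s to the six perturbable
# life-history traits, and maps of the most influential trait over the
# (p, q) switching-probability grid.

PERTURBABLE <- c("L_b", "L_p", "L_m", "R_m", "rB", "mu")

# Multiply one life-history trait by (1 + delta) and re-validate the
# parameter invariants. Perturbing L_b also moves the offspring mean,
# which is defined equal to L_b.
perturb_params <- function(params, parameter, delta) {
  stopifnot(inherits(params, "deb_params"))
  if (identical(parameter, "kappa")) {
    stop(paste("kappa is excluded from perturbation analysis: it is",
               "proportional to L_m and to (1 - kappa) in R_m, so its",
               "effects confound survival, growth and reproduction"),
         call. = FALSE)
  }
  if (!parameter %in% PERTURBABLE) {
    stop("parameter must be one of: ", paste(PERTURBABLE, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[[parameter]] <- p[[parameter]] * (1 + delta)
  if (parameter == "L_b") p$offspring_mean <- p$L_b
  do.call(deb_params, p)
}

#' Elasticity of log lambda_s to one life-history trait
#'
#' Proportional sensitivity computed by forward difference: the trait is
#' multiplied by \code{1 + delta} (default a 1\% perturbation), the
#' stochastic projection is rerun with the \emph{same} environment-state
#' sequence as the baseline (common random numbers), and
#' \deqn{e = [\log\lambda_s(\theta(1+\delta)) - \log\lambda_s(\theta)] /
#'   \log(1+\delta).}
#' The mesh and both kernels are rebuilt for the perturbed parameters,
#' so perturbing \code{L_m} moves the starvation cutoff consistently.
#'
#' The allocation fraction kappa is refused: it is mathematically
#' proportional to \code{L_m} and to \code{(1 - kappa)} within
#' \code{R_m}, so its perturbation confounds survival, growth and
#' reproduction.
#'
#' @param params A [deb_params()] object.
#' @param regime A [feeding_regime()].
#' @param config A [sim_config()]; its seed fixes the shared state
#'   sequence.
#' @param parameter_name One of \code{L_b, L_p, L_m, R_m, rB, mu}.
#' @param delta Perturbation fraction (default 0.01).
#' @param states Optional precomputed state sequence (shared by base and
#'   perturbed runs).
#' @param base_run Optional precomputed baseline [project()] result under
#'   \code{states}; avoids recomputing the baseline across traits.
#' @return An object of class \code{elasticity_record}: \code{parameter},
#'   \code{elasticity}, \code{delta}, \code{base_log_lambda_s},
#'   \code{perturbed_log_lambda_s}, \code{seed}.
#' @export
elasticity <- function(params, regime, config = sim_config(),
                       parameter_name, delta = 0.01,
                       states = NULL, base_run = NULL) {
  stopifnot(inherits(params, "deb_params"),
            inherits(regime, "feeding_regime"),
            inherits(config, "sim_config"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= -1 || delta == 0) {
    stop("delta must be a nonzero fraction > -1", call. = FALSE)
  }
  perturbed <- perturb_params(params, parameter_name, delta)
  if (is.null(states)) {
    states <- simulate_state_sequence(regime, config$total_steps, config$seed)
  }
  if (is.null(base_run)) {
    base_run <- project(params, regime, config, states = states)
  }
  pert_run <- project(perturbed, regime, config, states = states)
  structure(
    list(parameter = parameter_name,
         elasticity = (pert_run$log_lambda_s - base_run$log_lambda_s) /
           log1p(delta),
         delta = delta,
         base_log_lambda_s = base_run$log_lambda_s,
         perturbed_log_lambda_s = pert_run$log_lambda_s,
         seed = config$seed),
    class = "elasticity_record"
  )
}

#' @export
print.elasticity_record <- function(x, ...) {
  cat(sprintf("<elasticity_record> %s: e = %.4f (delta = %g, base log lambda_s = %.4f)\n",
              x$parameter, x$elasticity, x$delta, x$base_log_lambda_s))
  invisible(x)
}

#' Map of the most influential life-history trait over the (p, q) grid
#'
#' For each combination of switching probabilities, computes the
#' elasticity of log lambda_s to all six perturbable traits under one
#' shared environment realization (per-cell seed derived from the root
#' seed) and reports the trait with maximum absolute elasticity. Ties
#' (within 1e-12) are broken by the fixed order
#' \code{L_b, L_p, L_m, R_m, rB, mu} and flagged. All thirteen kernels
#' (baseline plus six perturbed pairs) are built once and reused across
#' cells, since they do not depend on p or q.
#'
#' @param params A [deb_params()] object.
#' @param regime_template A [feeding_regime()] supplying feeding levels
#'   and sigma; p, q overridden per cell.
#' @param p_values,q_values Switching probabilities in \code{(0, 1]}.
#' @param config A [sim_config()].
#' @param delta Perturbation fraction (default 0.01).
#' @return A data frame of class \code{elasticity_grid} with columns
#'   \code{p, q, rho, f}, one elasticity column per trait
#'   (\code{e_L_b}, ...), \code{dominant}, \code{tie}, \code{seed}.
#' @export
dominant_parameter_map <- function(params, regime_template, p_values,
                                   q_values, config = sim_config(),
                                   delta = 0.01) {
  stopifnot(inherits(params, "deb_params"),
            inherits(regime_template, "feeding_regime"),
            inherits(config, "sim_config"))
  if (any(p_values <= 0) || any(p_values > 1) ||
      any(q_values <= 0) || any(q_values > 1)) {
    stop("p_values and q_values must lie in (0, 1]", call. = FALSE)
  }
  base_kernels <- kernel_pair(params, regime_template, config$n_cells)
  pert_kernels <- lapply(PERTURBABLE, function(nm) {
    kernel_pair(perturb_params(params, nm, delta), regime_template,
                config$n_cells)
  })
  names(pert_kernels) <- PERTURBABLE

  cells <- expand.grid(p = p_values, q = q_values, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    regime_k <- feeding_regime(cells$p[k], cells$q[k],
                               regime_template$EY_low,
                               regime_template$EY_high,
                               regime_template$sigma_Y)
    cell_seed <- derive_seed(config$seed, k)
    states <- simulate_state_sequence(regime_k, config$total_steps, cell_seed)
    base <- project(params, regime_k, config, kernels = base_kernels,
                    states = states)
    e <- vapply(PERTURBABLE, function(nm) {
      pert <- project(perturb_params(params, nm, delta), regime_k, config,
                      kernels = pert_kernels[[nm]], states = states)
      (pert$log_lambda_s - base$log_lambda_s) / log1p(delta)
    }, numeric(1))
    best <- which.max(abs(e))
    tie <- sum(abs(abs(e) - abs(e[best])) < 1e-12) > 1L
    row <- data.frame(p = cells$p[k], q = cells$q[k],
                      rho = autocorrelation(regime_k),
                      f = good_state_frequency(regime_k))
    for (nm in PERTURBABLE) row[[paste0("e_", nm)]] <- e[[nm]]
    row$dominant <- PERTURBABLE[best]
    row$tie <- tie
    row$seed <- cell_seed
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  class(res) <- c("elasticity_grid", "data.frame")
  res
}

#' Reshape an elasticity grid to long format
#'
#' @param grid A [dominant_parameter_map()] result.
#' @return Data frame with columns \code{p, q, rho, f, parameter,
#'   elasticity}, one row per cell and trait.
#' @export
elasticity_long <- function(grid) {
  stopifnot(is.data.frame(grid))
  cols <- paste0("e_", PERTURBABLE)
  stopifnot(all(cols %in% names(grid)))
  do.call(rbind, lapply(seq_along(PERTURBABLE), function(i) {
    data.frame(p = grid$p, q = grid$q, rho = grid$rho, f = grid$f,
               parameter = PERTURBABLE[i], elasticity = grid[[cols[i]]])
  }))
}
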