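# Generators for every input the analysis needs, so all stages are
# testable without field data: the dummy survivorship series behind the
# mortality-rate estimate, field-style samples of pereon lengths and
# podomere counts, and the named feeding regimes of the two study
# species.

#' Dummy daily survivorship series
#'
#' Deterministic recursion \code{s(0) = 1, s(t+1) = s(t) - m s(t)} used
#' to estimate a monthly mortality rate from a daily mortality fraction
#' (see [estimate_monthly_mortality()]). The series is exactly
#' geometric: \code{s(t) = (1 - m)^t}.
#'
#' @param daily_mortality Daily mortality fraction m, strictly in (0, 1).
#' @param n_days Number of days to recurse (>= 1).
#' @return Data frame with columns \code{day} (0..n_days) and
#'   \code{survivors}.
#' @export
survival_series <- function(daily_mortality, n_days = 365) {
  m <- daily_mortality
  if (!is.numeric(m) || length(m) != 1L || !(m > 0 && m < 1)) {
    stop("daily_mortality must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_days) || n_days < 1) {
    stop("n_days must be >= 1", call. = FALSE)
  }
  n_days <- as.integer(n_days)
  data.frame(day = 0:n_days,
             survivors = cumprod(c(1, rep(1 - m, n_days))))
}

#' Synthetic field-style sample of pereon lengths and podomere counts
#'
#' Emulates a hand-collected amphipod sample: body lengths are drawn
#' from a two-component normal mixture around the preset's birth and
#' puberty lengths (field SDs 0.37 and 0.50 mm by default), inverted
#' through the pereon allometry, and paired with stage-consistent
#' podomere counts (juveniles on 4--11, matures on 12--21, uniform —
#' placeholder distributions, not biological ones).
#'
#' @param params A [deb_params()] object supplying the stage means.
#' @param n Sample size (>= 1; field samples ran 100--750 specimens).
#' @param seed Optional integer seed for reproducibility.
#' @param stage_mix Proportion of juveniles (default 0.5).
#' @param juvenile_sd,mature_sd Stage SDs of body length (mm).
#' @return Data frame with columns \code{pereon_length},
#'   \code{podomere_count}, \code{body_length}, \code{stage}.
#' @export
synthetic_sample <- function(params, n, seed = NULL, stage_mix = 0.5,
                             juvenile_sd = 0.37, mature_sd = 0.50) {
  stopifnot(inherits(params, "deb_params"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  stop_scalar_prob(stage_mix, "stage_mix")
  n <- as.integer(n)
  with_seed(seed, {
    juvenile <- stats::runif(n) < stage_mix
    mean_l <- ifelse(juvenile, params$L_b, params$L_p)
    sd_l <- ifelse(juvenile, juvenile_sd, mature_sd)
    body <- stats::rnorm(n, mean_l, sd_l)
    # lengths must invert through the allometry; redraw rare low tails
    bad <- which(body <= PEREON_INTERCEPT)
    while (length(bad)) {
      body[bad] <- stats::rnorm(length(bad), mean_l[bad], sd_l[bad])
      bad <- bad[body[bad] <= PEREON_INTERCEPT]
    }
    podomeres <- ifelse(juvenile,
                        sample(4:11, n, replace = TRUE),
                        sample(12:21, n, replace = TRUE))
    data.frame(
      pereon_length = body_to_pereon_length(body),
      podomere_count = podomeres,
      body_length = body,
      stage = ifelse(juvenile, "juvenile", "subadult_or_adult"))
  })
}

#' Named feeding regimes of the two study species
#'
#' The good/bad feeding levels bracket the deterministic equilibrium of
#' each species: for \emph{O. gammarellus} the bad state (E(Y) = 0.4)
#' puts the ultimate length below puberty so reproduction ceases, and
#' the good state is full feeding (1.0); for \emph{M. alfredi} the
#' states 0.5 and 0.9 bracket the equilibrium feeding level 0.75. Each
#' regime comes in a low (sigma(Y) = 0.1) and a high (0.5)
#' feeding-variability variant. Switching probabilities default to
#' white noise (p = q = 0.5) and are meant to be overridden by
#' [grid_sweep()].
#'
#' @return Named list of [feeding_regime()] objects:
#'   \code{orchestia_sigma_0.1}, \code{orchestia_sigma_0.5},
#'   \code{manta_sigma_0.1}, \code{manta_sigma_0.5}.
#' @export
default_regimes <- function() {
  list(
    orchestia_sigma_0.1 = feeding_regime(0.5, 0.5, 0.4, 1.0, 0.1),
    orchestia_sigma_0.5 = feeding_regime(0.5, 0.5, 0.4, 1.0, 0.5),
    manta_sigma_0.1 = feeding_regime(0.5, 0.5, 0.5, 0.9, 0.1),
    manta_sigma_0.5 = feeding_regime(0.5, 0.5, 0.5, 0.9, 0.5)
  )
}
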