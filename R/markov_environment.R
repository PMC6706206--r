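# Two-state Markov chain of good/bad feeding environments: regime object,
# transition matrix, noise-color descriptors, and sequence simulation.

#' Define a two-state Markov feeding regime
#'
#' The environment alternates between a good state (feeding level
#' \code{EY_high}) and a bad state (\code{EY_low}) under a first-order
#' Markov chain: \code{p} is the probability of switching from the good
#' to the bad environment and \code{q} the probability of switching from
#' bad to good. The chain's serial autocorrelation is
#' \code{rho = 1 - p - q} (positive: red noise; zero: white; negative:
#' blue) and the stationary frequency of the good state is
#' \code{f = q / (p + q)}.
#'
#' @param p Probability of switching good -> bad, in \code{[0, 1]}.
#' @param q Probability of switching bad -> good, in \code{[0, 1]}.
#' @param EY_low Expected feeding level of the bad state.
#' @param EY_high Expected feeding level of the good state; must be at
#'   least \code{EY_low} (equality gives a degenerate, constant
#'   environment, useful as a deterministic check).
#' @param sigma_Y Standard deviation of the feeding level; widens the
#'   growth kernel (the model's demographic-stochasticity channel).
#' @return An object of class \code{feeding_regime}.
#' @export
feeding_regime <- function(p, q, EY_low, EY_high, sigma_Y = 0.1) {
  stop_scalar_prob(p, "p")
  stop_scalar_prob(q, "q")
  stop_scalar_prob(EY_low, "EY_low")
  stop_scalar_prob(EY_high, "EY_high")
  if (EY_low > EY_high) stop("EY_low must not exceed EY_high", call. = FALSE)
  if (!is.numeric(sigma_Y) || length(sigma_Y) != 1L || sigma_Y < 0) {
    stop("sigma_Y must be a single nonnegative number", call. = FALSE)
  }
  structure(list(p = p, q = q, EY_low = EY_low, EY_high = EY_high,
                 sigma_Y = sigma_Y),
            class = "feeding_regime")
}

#' @export
print.feeding_regime <- function(x, ...) {
  cat("<feeding_regime>\n")
  cat(sprintf("  p = %g (good->bad), q = %g (bad->good)\n", x$p, x$q))
  cat(sprintf("  E(Y): bad %g, good %g; sigma(Y) = %g\n",
              x$EY_low, x$EY_high, x$sigma_Y))
  cat(sprintf("  rho = %g, f = %s\n", autocorrelation(x),
              if (x$p + x$q > 0) format(good_state_frequency(x)) else "undefined"))
  invisible(x)
}

#' Habitat transition matrix of the feeding regime
#'
#' Column-stochastic 2x2 matrix with state 1 = good, state 2 = bad:
#' column j holds the probabilities of moving from state j to each state.
#'
#' @param regime A [feeding_regime()].
#' @return A 2x2 matrix \code{[[1-p, q], [p, 1-q]]}.
#' @export
transition_matrix <- function(regime) {
  stopifnot(inherits(regime, "feeding_regime"))
  matrix(c(1 - regime$p, regime$p, regime$q, 1 - regime$q), nrow = 2,
         dimnames = list(to = c("good", "bad"), from = c("good", "bad")))
}

#' Serial autocorrelation (noise color) of the regime
#'
#' @param regime A [feeding_regime()].
#' @return \code{1 - p - q}, in \code{[-1, 1]}.
#' @export
autocorrelation <- function(regime) {
  stopifnot(inherits(regime, "feeding_regime"))
  1 - regime$p - regime$q
}

#' Stationary frequency of the good environment
#'
#' @param regime A [feeding_regime()].
#' @return \code{q / (p + q)}.
#' @export
good_state_frequency <- function(regime) {
  stopifnot(inherits(regime, "feeding_regime"))
  if (regime$p + regime$q <= 0) {
    stop("good-state frequency undefined for p = q = 0 (frozen chain)",
         call. = FALSE)
  }
  regime$q / (regime$p + regime$q)
}

#' Simulate a sequence of environment states
#'
#' The initial state is drawn uniformly at random from \{good, bad\};
#' each subsequent state follows the regime's transition matrix.
#'
#' @param regime A [feeding_regime()].
#' @param length Number of timesteps (>= 1).
#' @param seed Optional integer seed; a fixed seed gives bit-identical
#'   sequences. The caller's RNG stream is left untouched.
#' @return Integer vector of states, 1 = good, 2 = bad.
#' @export
simulate_state_sequence <- function(regime, length, seed = NULL) {
  stopifnot(inherits(regime, "feeding_regime"))
  if (!is.numeric(length) || length < 1) stop("length must be >= 1", call. = FALSE)
  length <- as.integer(length)
  p <- regime$p
  q <- regime$q
  with_seed(seed, {
    s <- integer(length)
    s[1] <- sample(2L, 1L)
    if (length > 1L) {
      u <- stats::runif(length - 1L)
      for (t in seq_len(length - 1L)) {
        s[t + 1L] <- if (s[t] == 1L) {
          if (u[t] < p) 2L else 1L
        } else {
          if (u[t] < q) 1L else 2L
        }
      }
    }
    s
  })
}

#' Write a state sequence to a delimited file
#'
#' @param states Integer state vector from [simulate_state_sequence()].
#' @param path Output path (tab-separated, columns \code{time},
#'   \code{state}).
#' @return `path`, invisibly.
#' @export
write_state_sequence <- function(states, path) {
  utils::write.table(
    data.frame(time = seq_along(states), state = states),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
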