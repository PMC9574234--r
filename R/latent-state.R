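#' Simulate a latent attentional-state trajectory
#'
#' The generator assumes mind wandering waxes and wanes in slowly
#' fluctuating episodes. The latent state is a discretized
#' Ornstein-Uhlenbeck (OU) process passed through a logistic map, giving a
#' bounded, autocorrelated intensity in (0, 1): 0 = fully on task,
#' 1 = deeply off task. On the OU scale the exact discretization
#' `x[t+dt] = mu + phi * (x[t] - mu) + e`, `phi = exp(-dt/tau)`,
#' `e ~ N(0, sigma^2 * tau/2 * (1 - phi^2))` is used, so the stationary SD
#' is `sigma * sqrt(tau/2)` and the lag-`dt` autocorrelation is
#' `exp(-dt/tau)`.
#'
#' @param duration trajectory length in seconds (> 0).
#' @param params list with elements `tau` (mean-reversion time constant,
#'   seconds, default 30), `mu` (OU mean, default 0), `sigma` (diffusion
#'   scale, default 0.25), `dt` (sampling step, seconds, default 0.25),
#'   `x0` (optional start value on the OU scale; default `mu`).
#' @param seed integer seed; the trajectory is deterministic given it.
#' @return object of class `latent_state`: list with `times`, `state`
#'   (logistic-transformed, in (0,1)), `x` (OU scale) and the parameters.
#' @examples
#' traj <- simulate_latent_state(60, seed = 1)
#' range(traj$state)
#' @export
simulate_latent_state <- function(duration, params = list(), seed = 1L) {
  stopifnot(duration > 0)
  p <- utils::modifyList(
    list(tau = 30, mu = 0, sigma = 0.25, dt = 0.25, x0 = NULL), params)
  if (p$tau <= 0 || p$dt <= 0) stop("time constants must be positive")
  if (p$sigma < 0) stop("sigma must be non-negative")
  set.seed(seed)
  times <- seq(0, duration, by = p$dt)
  n <- length(times)
  phi <- exp(-p$dt / p$tau)
  innov_sd <- p$sigma * sqrt(p$tau / 2 * (1 - phi^2))
  x <- numeric(n)
  x[1] <- if (is.null(p$x0)) p$mu else p$x0
  eps <- stats::rnorm(n - 1L, 0, innov_sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- p$mu + phi * (x[i] - p$mu) + eps[i]
  out <- list(times = times, state = stats::plogis(x), x = x, params = p)
  class(out) <- "latent_state"
  out
}

#' Evaluate a latent-state trajectory at arbitrary times
#'
#' Linear interpolation, constant beyond the ends.
#'
#' @param traj a [simulate_latent_state()] result.
#' @param at times in seconds.
#' @return state values in (0, 1).
#' @export
state_at <- function(traj, at) {
  stats::approx(traj$times, traj$state, xout = at, rule = 2)$y
}

#' Subject-level generating parameters
#'
#' Houses everything subject-specific in the generator: the probit random
#' intercept, tapping-noise base level and its coupling to the latent state,
#' the repetition-bias coupling, pupil amplitudes/time constants, and the
#' blink rate.
#'
#' `rep_bias_gain` controls how strongly the hand-choice distribution drifts
#' away from the maximally random 50/50 alternation probability as the
#' state rises; `iti_sd_gain` adds tapping-time jitter as the state rises,
#' producing the study's empirical signature (higher variability, lower
#' sequence entropy before off-task reports).
#'
#' @param intercept_shift subject random intercept on the latent probit
#'   scale.
#' @param iti_sd_base baseline tap-timing jitter SD, seconds (> 0).
#' @param iti_sd_gain added jitter SD per unit state, seconds.
#' @param rep_bias_gain probability units of repetition bias per unit state;
#'   the realized bias is clamped into [0, 0.5].
#' @param pupil_params list: `baseline` (a.u.), `tonic_amp` (a.u.),
#'   `tonic_tau` (s), `phasic_amp` (a.u.), `decoupling` (fractional phasic
#'   shrinkage per unit state, in [0,1]), `noise_sd` (a.u.),
#'   `state_gain` (a.u. tonic shift per unit state).
#' @param blink_rate blinks per minute.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(intercept_shift = 0,
                           iti_sd_base = 0.020,
                           iti_sd_gain = 0.080,
                           rep_bias_gain = 0.9,
                           pupil_params = list(),
                           blink_rate = 12) {
  if (iti_sd_base <= 0) stop("iti_sd_base must be positive")
  if (blink_rate < 0) stop("blink_rate must be non-negative")
  pp <- utils::modifyList(
    list(baseline = 1000, tonic_amp = 40, tonic_tau = 20,
         phasic_amp = 25, decoupling = 0.6, noise_sd = 2, state_gain = -30),
    pupil_params)
  out <- list(intercept_shift = intercept_shift,
              iti_sd_base = iti_sd_base,
              iti_sd_gain = iti_sd_gain,
              rep_bias_gain = rep_bias_gain,
              pupil_params = pp,
              blink_rate = blink_rate)
  class(out) <- "subject_params"
  out
}

# repetition bias at a given state level; p(alternate) = 1 - rep_bias.
# At state 0 the bias is 0.5 (p_alt = 0.5, maximal sequence entropy); as the
# state rises the bias falls toward 0 so the sequence drifts toward
# predictable strict alternation and approximate entropy drops.
rep_bias <- function(state, gain) {
  pmin(pmax(0.5 - gain * state, 0.02), 0.5)
}
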