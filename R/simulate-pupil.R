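#' Simulate a pupil trace with tonic drift, PRF responses and blinks
#'
#' The generative model mirrors the deconvolution analysis: a slow tonic
#' baseline (an OU-filtered drift plus a state-coupled shift), one
#' pupil-response-function (PRF) shaped transient per task event whose
#' amplitude shrinks as the latent state rises (perceptual decoupling),
#' additive white noise, and blink dropouts (runs of missing samples) at
#' Poisson times.
#'
#' @param state a `latent_state` trajectory covering the trace span.
#' @param events data.frame with `onset` (s, sorted) and `type`
#'   ("stimulus"/"tap"); both event types evoke PRF responses.
#' @param subject a [subject_params()]; its `pupil_params` set amplitudes,
#'   time constants, decoupling, noise and `blink_rate` the dropout rate.
#' @param config a [sim_config()]; `pupil_fs` sets the sampling rate.
#' @param seed integer seed.
#' @param duration trace length in seconds (default: spans all events + 4 s).
#' @return object of class `pupil_trace`: list with `time`, `size` (a.u.,
#'   NA during blinks), `fs`, `mask` (0 valid, 2 missing), `events`, and
#'   `truth` (tonic curve, per-event amplitudes, blink intervals).
#' @export
simulate_pupil <- function(state, events, subject, config, seed = 1L,
                           duration = NULL) {
  fs <- config$pupil_fs
  if (fs <= 0) stop("pupil_fs must be positive")
  if (is.unsorted(events$onset)) stop("events must be sorted by onset")
  pp <- subject$pupil_params
  if (is.null(duration)) duration <- max(events$onset) + 4
  set.seed(seed)
  n <- floor(duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs

  # tonic: OU drift simulated on a coarse 2 s grid and spline-interpolated,
  # so the baseline is genuinely smooth at the sampling rate
  t_coarse <- seq(0, duration + 2, by = 2)
  phi <- exp(-1 / pp$tonic_tau)
  innov_sd <- sqrt(1 - phi^2)          # unit stationary variance
  z <- stats::filter(stats::rnorm(length(t_coarse), 0, innov_sd), phi,
                     method = "recursive", init = stats::rnorm(1))
  drift <- stats::spline(t_coarse, as.numeric(z), xout = tt)$y
  tonic <- pp$baseline + pp$tonic_amp * drift +
    pp$state_gain * (state_at(state, tt) - 0.5)

  # phasic: PRF kernel per event, amplitude scaled down with the state
  amp <- pp$phasic_amp * (1 - pp$decoupling * state_at(state, events$onset))
  kern_t <- seq(0, 4, by = 1 / fs)
  kern <- prf(kern_t * 1000)
  phasic <- numeric(n)
  idx0 <- round(events$onset * fs) + 1L
  for (j in seq_along(idx0)) {
    i1 <- idx0[j]
    if (i1 > n) next
    i2 <- min(n, i1 + length(kern) - 1L)
    phasic[i1:i2] <- phasic[i1:i2] + amp[j] * kern[seq_len(i2 - i1 + 1L)]
  }

  size <- tonic + phasic +
    if (pp$noise_sd > 0) stats::rnorm(n, 0, pp$noise_sd) else 0
  mask <- integer(n)

  blinks <- NULL
  if (subject$blink_rate > 0) {
    n_blinks <- stats::rpois(1, subject$blink_rate * duration / 60)
    if (n_blinks > 0) {
      on <- sort(stats::runif(n_blinks, 0, duration - 0.5))
      len <- stats::runif(n_blinks, 0.10, 0.30)
      blinks <- data.frame(onset = on, offset = pmin(on + len, duration))
      for (j in seq_len(n_blinks)) {
        sel <- tt >= blinks$onset[j] & tt <= blinks$offset[j]
        size[sel] <- NA_real_
        mask[sel] <- 2L
      }
    }
  }

  out <- list(time = tt, size = size, fs = fs, mask = mask, events = events,
              truth = list(tonic = tonic, amplitudes = amp, blinks = blinks))
  class(out) <- "pupil_trace"
  out
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("pupil_trace: %d samples @ %g Hz (%.1f s), %.1f%% missing, %d events\n",
              length(x$size), x$fs, length(x$size) / x$fs,
              100 * mean(x$mask == 2L),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Simulate 4D BOLD data from a design matrix and a coefficient map
#'
#' Voxel time series are `X %*% beta_voxel` plus serially independent
#' Gaussian noise, enabling exact-recovery and null-calibration tests of
#' the GLM machinery.
#'
#' @param design numeric matrix, volumes x regressors.
#' @param truth_map 4D array `dims x ncol(design)` of voxelwise
#'   coefficients (the last dimension indexes regressors).
#' @param noise_sd noise SD; 0 gives a noiseless dataset.
#' @param seed integer seed.
#' @return 4D array `dims x nrow(design)` (last dimension = time).
#' @export
simulate_bold <- function(design, truth_map, noise_sd = 1, seed = 1L) {
  design <- as.matrix(design)
  d <- dim(truth_map)
  if (length(d) != 4 || d[4] != ncol(design))
    stop("truth_map must be 4D with last dimension matching design columns")
  n_vox <- prod(d[1:3])
  beta <- matrix(truth_map, nrow = n_vox)           # n_vox x p
  set.seed(seed)
  y <- beta %*% t(design)                           # n_vox x T
  if (noise_sd > 0) y <- y + matrix(stats::rnorm(length(y), 0, noise_sd),
                                    nrow = n_vox)
  array(y, dim = c(d[1:3], nrow(design)))
}
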