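#' Simulation configuration for an FT-RSGT session
#'
#' Bundles the design constants of the finger-tapping random-sequence
#' generation task: block counts, metronome pacing, per-block stimulus
#' counts, probe timing, and sampling rates. Defaults reproduce the study
#' design: 18 random + 9 alternating blocks per subject, one auditory
#' metronome stimulus every 750 ms, 80 stimuli per block on average
#' (range 74-87) so thought probes land between 55.5 and 65.25 s after
#' tapping onset (60 s on average), probes shown for 6 s plus 0-1 s jitter,
#' and a 4 s instruction screen per block.
#'
#' @param n_subjects number of subjects.
#' @param n_random_blocks experimental (random tapping) blocks per subject.
#' @param n_alternating_blocks control (alternating) blocks per subject.
#' @param soa metronome stimulus-onset asynchrony in seconds.
#' @param stimuli_per_block_mean target mean stimulus count per block.
#' @param stimuli_per_block_range integer `c(min, max)` support of the
#'   per-block stimulus-count distribution.
#' @param probe_display probe display duration in seconds.
#' @param probe_jitter_max maximum uniform jitter added to probe display, s.
#' @param instruction_duration instruction-screen duration in seconds.
#' @param pupil_fs sampling rate of simulated pupil traces, Hz.
#' @param tr fMRI repetition time in seconds.
#' @param seed master integer seed; every stochastic stage derives its own
#'   stream from it via [split_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 2, seed = 7)
#' cfg$soa
#' @export
sim_config <- function(n_subjects = 27,
                       n_random_blocks = 18,
                       n_alternating_blocks = 9,
                       soa = 0.750,
                       stimuli_per_block_mean = 80,
                       stimuli_per_block_range = c(74L, 87L),
                       probe_display = 6,
                       probe_jitter_max = 1,
                       instruction_duration = 4,
                       pupil_fs = 100,
                       tr = 1.8,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_random_blocks >= 1, n_alternating_blocks >= 0)
  if (soa <= 0 || probe_display <= 0 || instruction_duration <= 0 ||
      pupil_fs <= 0 || tr <= 0 || probe_jitter_max < 0)
    stop("all durations and rates must be positive")
  rng <- as.integer(round(stimuli_per_block_range))
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 2)
    stop("invalid stimuli_per_block_range")
  if (stimuli_per_block_mean < rng[1] || stimuli_per_block_mean > rng[2])
    stop("stimuli_per_block_mean outside stimuli_per_block_range")
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_random_blocks = as.integer(n_random_blocks),
    n_alternating_blocks = as.integer(n_alternating_blocks),
    soa = soa,
    stimuli_per_block_mean = stimuli_per_block_mean,
    stimuli_per_block_range = rng,
    probe_display = probe_display,
    probe_jitter_max = probe_jitter_max,
    instruction_duration = instruction_duration,
    pupil_fs = pupil_fs,
    tr = tr,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("FT-RSGT simulation config\n")
  cat(sprintf("  subjects: %d  blocks: %d random + %d alternating\n",
              x$n_subjects, x$n_random_blocks, x$n_alternating_blocks))
  cat(sprintf("  SOA %.3f s, stimuli/block mean %.1f in [%d, %d]\n",
              x$soa, x$stimuli_per_block_mean,
              x$stimuli_per_block_range[1], x$stimuli_per_block_range[2]))
  cat(sprintf("  probe %.1f s (+ up to %.1f s jitter), instructions %.1f s\n",
              x$probe_display, x$probe_jitter_max, x$instruction_duration))
  cat(sprintf("  pupil fs %g Hz, TR %.2f s, seed %d\n",
              x$pupil_fs, x$tr, x$seed))
  invisible(x)
}

#' Per-block stimulus-count distribution
#'
#' The study reports only the mean (80) and range (74-87) of stimuli per
#' block. We use a discrete triangular weight peaked at the target mean,
#' exponentially tilted so the distribution's mean equals
#' `stimuli_per_block_mean` exactly.
#'
#' @param config a [sim_config()].
#' @return data.frame with integer `count` and probability `p`.
#' @export
stimulus_count_distribution <- function(config) {
  rng <- config$stimuli_per_block_range
  mu <- config$stimuli_per_block_mean
  k <- rng[1]:rng[2]
  half <- max(mu - rng[1], rng[2] - mu) + 1
  base <- 1 - abs(k - mu) / half   # triangular, peak at mu, > 0 on support
  tilted_mean <- function(theta) {
    w <- base * exp(theta * (k - mu))
    sum(k * w) / sum(w) - mu
  }
  theta <- if (abs(tilted_mean(0)) < 1e-12) 0 else
    stats::uniroot(tilted_mean, c(-2, 2), tol = 1e-12)$root
  w <- base * exp(theta * (k - mu))
  data.frame(count = k, p = w / sum(w))
}
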