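#' Simulate the block structure of one session
#'
#' Draws per-block stimulus counts from the calibrated count distribution
#' (see [stimulus_count_distribution()]), lays blocks out sequentially
#' (instruction screen, metronome stimuli at multiples of the SOA, thought
#' probe one SOA after the last stimulus, probe display plus jitter), and
#' orders conditions by a uniform random permutation constrained so that no
#' two alternating blocks are consecutive.
#'
#' Within a block, stimulus k (k = 1..n) occurs at `(k-1) * soa` after
#' tapping onset, so the probe onset relative to tapping onset is
#' `n * soa`: 55.5-65.25 s for counts in 74-87, 60 s at the mean of 80.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config's blocks stream).
#' @return data.frame, one row per block: `block`, `condition`
#'   ("random"/"alternating"), `n_stimuli`, `block_start` (session s),
#'   `tapping_start` (session s of the first stimulus), `probe_onset_block`
#'   (s after tapping onset), `probe_onset` (session s), `block_end`
#'   (session s). Attribute `stim_onsets`: list of session-time stimulus
#'   onset vectors.
#' @export
simulate_block_structure <- function(config,
                                     seed = split_seed(config$seed,
                                                       .stage[["blocks"]])) {
  dist <- stimulus_count_distribution(config)
  n_r <- config$n_random_blocks
  n_a <- config$n_alternating_blocks
  n_blocks <- n_r + n_a
  if (n_a > n_r + 1)
    stop("cannot order blocks without consecutive alternating blocks")
  set.seed(seed)
  cond <- c(rep("random", n_r), rep("alternating", n_a))
  repeat {
    ord <- sample(cond)
    if (n_a <= 1 ||
        !any(ord[-1] == "alternating" & ord[-n_blocks] == "alternating"))
      break
  }
  counts <- dist$count[sample.int(nrow(dist), n_blocks, replace = TRUE,
                                  prob = dist$p)]
  jitter <- stats::runif(n_blocks, 0, config$probe_jitter_max)

  block_start <- numeric(n_blocks)
  stim_onsets <- vector("list", n_blocks)
  tapping_start <- probe_onset <- block_end <- numeric(n_blocks)
  t0 <- 0
  for (b in seq_len(n_blocks)) {
    block_start[b] <- t0
    tapping_start[b] <- t0 + config$instruction_duration
    stim_onsets[[b]] <- tapping_start[b] + (seq_len(counts[b]) - 1) * config$soa
    probe_onset[b] <- tapping_start[b] + counts[b] * config$soa
    block_end[b] <- probe_onset[b] + config$probe_display + jitter[b]
    t0 <- block_end[b]
  }
  out <- data.frame(block = seq_len(n_blocks),
                    condition = ord,
                    n_stimuli = counts,
                    block_start = block_start,
                    tapping_start = tapping_start,
                    probe_onset_block = counts * config$soa,
                    probe_onset = probe_onset,
                    block_end = block_end,
                    stringsAsFactors = FALSE)
  attr(out, "stim_onsets") <- stim_onsets
  out
}

#' Simulate the tap stream of one block
#'
#' One tap per metronome stimulus by default: tap time = stimulus onset plus
#' Gaussian jitter with SD `iti_sd_base + iti_sd_gain * state`, hand chosen
#' by strict alternation in alternating blocks and by a state-dependent
#' alternation probability `1 - rep_bias(state)` in random blocks. Optional
#' missing- and double-tap injection emulates the unfiltered raw stream the
#' study analyzed.
#'
#' @param state a `latent_state` trajectory (session time base).
#' @param stim_onsets stimulus onsets of the block, session seconds, sorted.
#' @param subject a [subject_params()].
#' @param condition "random" or "alternating".
#' @param seed integer seed.
#' @param p_missing,p_double per-stimulus probabilities of a missed or a
#'   doubled tap (defaults 0).
#' @return data.frame `time` (s, sorted), `hand` ("L"/"R"), `stimulus`
#'   (index of the pacing stimulus, NA-free).
#' @export
simulate_taps <- function(state, stim_onsets, subject, condition = "random",
                          seed = 1L, p_missing = 0, p_double = 0) {
  if (length(stim_onsets) == 0) stop("block has no stimulus onsets")
  set.seed(seed)
  s <- state_at(state, stim_onsets)
  sdv <- subject$iti_sd_base + subject$iti_sd_gain * s
  n <- length(stim_onsets)
  times <- stim_onsets + stats::rnorm(n, 0, sdv)
  if (condition == "alternating") {
    hands <- rep(c("L", "R"), length.out = n)
  } else {
    p_alt <- 1 - rep_bias(s, subject$rep_bias_gain)
    hands <- character(n)
    hands[1] <- sample(c("L", "R"), 1)
    flips <- stats::runif(n - 1) < p_alt[-1]
    for (i in seq_len(n - 1)) {
      hands[i + 1] <- if (flips[i]) setdiff(c("L", "R"), hands[i]) else hands[i]
    }
  }
  keep <- stats::runif(n) >= p_missing
  dup <- stats::runif(n) < p_double
  df <- data.frame(time = times, hand = hands, stimulus = seq_len(n),
                   stringsAsFactors = FALSE)
  extra <- df[dup & keep, , drop = FALSE]
  if (nrow(extra)) extra$time <- extra$time + abs(stats::rnorm(nrow(extra), 0.1, 0.03))
  df <- rbind(df[keep, , drop = FALSE], extra)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Draw ordinal thought-probe responses from the ordered-probit generative
#' model
#'
#' Latent `y* = x %*% beta + u + eps`, `eps ~ N(0, 1)`; the response is the
#' category whose cutpoint interval brackets `y*` (cutpoints `c_1 < ... <
#' c_{K-1}`, categories `1..K`).
#'
#' @param x numeric matrix of covariates (rows = probes).
#' @param betas coefficient vector, `length(betas) == ncol(x)`.
#' @param cutpoints strictly increasing cutpoint vector (length K-1).
#' @param u subject intercept, scalar or one value per row.
#' @param seed integer seed.
#' @return integer responses in `1..K`.
#' @export
simulate_probe_response <- function(x, betas, cutpoints, u = 0, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(betas))
  if (any(diff(cutpoints) <= 0)) stop("cutpoints must be strictly increasing")
  set.seed(seed)
  eta <- drop(x %*% betas) + u
  ystar <- eta + stats::rnorm(nrow(x))
  findInterval(ystar, cutpoints) + 1L
}

#' Default session-level generative parameters
#'
#' Coefficients linking the latent state and time-on-task to thought-probe
#' responses, plus cutpoints calibrated so the marginal response
#' distribution resembles the study's (mean response near 2.9 on the
#' 6-point scale, roughly 36% of responses in the three off-task
#' categories).
#'
#' @return list with `beta_time`, `beta_state`, `cutpoints`, `sigma_u`.
#' @export
session_response_params <- function() {
  list(beta_time = 0.35,       # per z-scored probe number
       beta_state = 0.90,      # per z-scored latent state at probe
       cutpoints = c(-1.25, -0.30, 0.53, 1.25, 2.08),
       sigma_u = 0.5)
}

#' Simulate a complete FT-RSGT session cohort
#'
#' Generates, for every subject: a latent attentional-state trajectory,
#' the block layout, the tap stream of every block, ordinal thought-probe
#' responses drawn from the ordered-probit generative model (covariates:
#' z-scored probe number and z-scored latent state at the probe; subject
#' random intercepts with SD `sigma_u`), and optionally a pupil trace.
#' All generating parameters and trajectories are retained under `$truth`.
#'
#' @param config a [sim_config()].
#' @param subjects optional list of [subject_params()] (length
#'   `n_subjects`); by default subject intercepts are drawn from
#'   `N(0, sigma_u^2)` and the remaining parameters are shared.
#' @param response_params see [session_response_params()].
#' @param include_pupil simulate pupil traces (heavier; default FALSE).
#' @param p_missing,p_double tap-injection rates passed to [simulate_taps()].
#' @return object of class `ftrsgt_session`: list with `config`,
#'   `subjects` (list, one element per subject with `blocks`, `taps`,
#'   `probes`, optional `pupil`, `state`), and `truth`.
#' @export
simulate_session <- function(config = sim_config(),
                             subjects = NULL,
                             response_params = session_response_params(),
                             include_pupil = FALSE,
                             p_missing = 0, p_double = 0) {
  rp <- response_params
  n_sub <- config$n_subjects
  if (is.null(subjects)) {
    set.seed(split_seed(config$seed, .stage[["probes"]], 0L))
    ints <- stats::rnorm(n_sub, 0, rp$sigma_u)
    subjects <- lapply(ints, function(i) subject_params(intercept_shift = i))
  }
  stopifnot(length(subjects) == n_sub)

  n_blocks <- config$n_random_blocks + config$n_alternating_blocks
  out_sub <- vector("list", n_sub)
  for (si in seq_len(n_sub)) {
    sp <- subjects[[si]]
    blocks <- simulate_block_structure(
      config, seed = split_seed(config$seed, .stage[["blocks"]], si))
    dur <- max(blocks$block_end)
    state <- simulate_latent_state(
      dur, seed = split_seed(config$seed, .stage[["latent"]], si))
    onsets <- attr(blocks, "stim_onsets")
    taps <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      taps[[b]] <- simulate_taps(
        state, onsets[[b]], sp, blocks$condition[b],
        seed = split_seed(config$seed, .stage[["taps"]], si, b),
        p_missing = p_missing, p_double = p_double)
      taps[[b]]$block <- b
    }
    taps <- do.call(rbind, taps)

    probe_state <- state_at(state, blocks$probe_onset)
    time_z <- as.numeric(scale(seq_len(n_blocks)))
    state_z <- as.numeric(scale(probe_state))
    xmat <- cbind(time = time_z, state = state_z)
    resp <- simulate_probe_response(
      xmat, c(rp$beta_time, rp$beta_state), rp$cutpoints,
      u = sp$intercept_shift,
      seed = split_seed(config$seed, .stage[["probes"]], si))
    probes <- data.frame(block = blocks$block,
                         condition = blocks$condition,
                         probe_onset = blocks$probe_onset,
                         probe_index = seq_len(n_blocks),
                         response = resp,
                         state_truth = probe_state)

    pupil <- NULL
    if (include_pupil) {
      ev <- data.frame(
        onset = c(unlist(onsets), taps$time),
        type = c(rep("stimulus", length(unlist(onsets))),
                 rep("tap", nrow(taps))))
      ev <- ev[order(ev$onset), ]
      pupil <- simulate_pupil(
        state, ev, sp, config,
        seed = split_seed(config$seed, .stage[["pupil"]], si))
    }
    out_sub[[si]] <- list(subject = si, params = sp, blocks = blocks,
                          taps = taps, probes = probes, state = state,
                          pupil = pupil)
  }
  out <- list(config = config, subjects = out_sub,
              truth = list(response_params = rp,
                           intercepts = vapply(subjects,
                                               `[[`, numeric(1),
                                               "intercept_shift")))
  class(out) <- "ftrsgt_session"
  out
}

#' @export
print.ftrsgt_session <- function(x, ...) {
  nb <- x$config$n_random_blocks + x$config$n_alternating_blocks
  cat(sprintf("Simulated FT-RSGT cohort: %d subjects x %d blocks (%d random, %d alternating)\n",
              x$config$n_subjects, nb,
              x$config$n_random_blocks, x$config$n_alternating_blocks))
  cat(sprintf("  pupil traces: %s\n",
              if (is.null(x$subjects[[1]]$pupil)) "no" else "yes"))
  invisible(x)
}
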