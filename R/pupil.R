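#' Pupil-response function (PRF)
#'
#' Erlang-like kernel `h(t) = t^n * exp(-n * t / t_max)` describing the
#' event-evoked pupil dilation, with shape `n = 10` and peak latency
#' `t_max = 900` ms. The kernel is rescaled to unit peak so that fitted
#' coefficients are amplitudes in signal units (the source only fixes the
#' shape). Computed as `(t/t_max)^n * exp(n * (1 - t/t_max))` for numerical
#' stability; negative times map to 0.
#'
#' @param t_ms time in milliseconds (vector).
#' @param n shape parameter.
#' @param t_max peak latency in milliseconds.
#' @return kernel values, peak value 1 at `t = t_max`.
#' @examples
#' prf(900)  # 1
#' @export
prf <- function(t_ms, n = 10, t_max = 900) {
  if (n <= 0 || t_max <= 0) stop("n and t_max must be positive")
  r <- t_ms / t_max
  out <- ifelse(t_ms <= 0, 0, r^n * exp(n * (1 - r)))
  out[t_ms == 0] <- 0
  out
}

#' Detect blinks from the pupil velocity profile
#'
#' Blink onsets are detected where the smoothed first difference of the
#' pupil signal drops below `-k * robust SD` (rapid constriction /
#' signal collapse) and offsets where it next returns from above
#' `+k * robust SD` (rebound). The robust SD is the MAD of the velocity,
#' making the thresholds subject-specific. Runs of missing samples are
#' always included as blink intervals. Intervals closer than
#' `merge_distance` are merged.
#'
#' @param trace a `pupil_trace` (list with `size`, `fs`; NAs = missing).
#' @param k threshold in robust SDs of the velocity (default 5).
#' @param smooth_ms width of the moving-average velocity smoother, ms.
#' @param merge_distance maximum gap between consecutive blinks that are
#'   merged, seconds (default 0.2).
#' @return data.frame `onset`, `offset` (seconds), disjoint and sorted;
#'   zero rows if none.
#' @export
detect_blinks <- function(trace, k = 5, smooth_ms = 20,
                          merge_distance = 0.2) {
  x <- trace$size; fs <- trace$fs
  if (length(x) == 0) stop("empty trace")
  v <- c(0, diff(x))
  w <- max(1L, round(smooth_ms / 1000 * fs))
  if (w > 1) {
    kern <- rep(1 / w, w)
    v_f <- stats::filter(ifelse(is.na(v), 0, v), kern, sides = 2)
    v <- as.numeric(v_f)
    v[is.na(v)] <- 0
  } else v[is.na(v)] <- 0
  s <- stats::mad(v[!is.na(trace$size)], na.rm = TRUE)
  ints <- NULL
  if (is.finite(s) && s > 0) {
    below <- v < -k * s
    above <- v > k * s
    i <- 1L; n <- length(x)
    starts <- ends <- integer(0)
    while (i <= n) {
      if (below[i]) {
        j <- i
        while (j <= n && !(above[j] &&
                           (j == n || !above[min(j + 1L, n)]))) j <- j + 1L
        starts <- c(starts, i); ends <- c(ends, min(j, n))
        i <- min(j, n) + 1L
      } else i <- i + 1L
    }
    if (length(starts))
      ints <- cbind((starts - 1) / fs, (ends - 1) / fs)
  }
  # missing-data runs always count as blinks
  na_run <- rle(is.na(x))
  if (any(na_run$values)) {
    e <- cumsum(na_run$lengths); b <- e - na_run$lengths + 1L
    sel <- na_run$values
    ints <- rbind(ints, cbind((b[sel] - 1) / fs, (e[sel] - 1) / fs))
  }
  if (is.null(ints) || nrow(ints) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  merge_blinks(data.frame(onset = ints[, 1], offset = ints[, 2]),
               merge_distance)
}

#' Merge nearby blink intervals
#'
#' @param blinks data.frame `onset`, `offset` (s).
#' @param merge_distance maximum gap (s) across which two intervals are
#'   merged into one.
#' @return sorted, disjoint intervals.
#' @export
merge_blinks <- function(blinks, merge_distance = 0.2) {
  if (nrow(blinks) == 0) return(blinks)
  b <- blinks[order(blinks$onset), , drop = FALSE]
  on <- b$onset[1]; off <- b$offset[1]
  outs <- list()
  for (i in seq_len(nrow(b))[-1]) {
    if (b$onset[i] - off <= merge_distance) {
      off <- max(off, b$offset[i])
    } else {
      outs[[length(outs) + 1L]] <- c(on, off)
      on <- b$onset[i]; off <- b$offset[i]
    }
  }
  outs[[length(outs) + 1L]] <- c(on, off)
  m <- do.call(rbind, outs)
  data.frame(onset = m[, 1], offset = m[, 2])
}

#' Linearly interpolate across blinks
#'
#' Each blink interval, widened by `margin` on both sides, is replaced by
#' the straight line between the nearest valid samples; interpolated
#' samples are flagged in the mask (1). Intervals touching the trace edge
#' are extended with the nearest valid value.
#'
#' @param trace a `pupil_trace`.
#' @param blinks data.frame `onset`, `offset` from [detect_blinks()].
#' @param margin seconds added around each interval (default 0.1).
#' @return the trace with `size` gap-free and `mask` updated
#'   (0 valid, 1 interpolated).
#' @export
interpolate_blinks <- function(trace, blinks, margin = 0.1) {
  x <- trace$size; fs <- trace$fs; n <- length(x)
  mask <- integer(n)
  bad <- is.na(x)
  if (nrow(blinks)) {
    for (i in seq_len(nrow(blinks))) {
      i1 <- max(1L, floor((blinks$onset[i] - margin) * fs) + 1L)
      i2 <- min(n, ceiling((blinks$offset[i] + margin) * fs) + 1L)
      bad[i1:i2] <- TRUE
    }
  }
  if (any(bad)) {
    mask[bad] <- 1L
    good <- which(!bad)
    if (length(good) < 2) stop("trace has no valid samples to interpolate from")
    x[bad] <- stats::approx(good, x[good], xout = which(bad), rule = 2)$y
  }
  trace$size <- x
  trace$mask <- mask
  trace
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-2 Butterworth applied forward and backward
#' ([signal::filtfilt()]), giving zero phase shift and preserving DC.
#'
#' @param trace a `pupil_trace` (gap-free `size`).
#' @param cutoff cutoff frequency in Hz, must be below `fs / 2`.
#' @param order filter order before the two-pass application (default 2).
#' @return the trace, filtered.
#' @export
lowpass <- function(trace, cutoff = 5, order = 2) {
  if (cutoff <= 0 || cutoff >= trace$fs / 2)
    stop("cutoff must lie in (0, fs/2)")
  if (anyNA(trace$size)) stop("interpolate blinks before filtering")
  bf <- signal::butter(order, cutoff / (trace$fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  x <- trace$size
  n <- length(x)
  np <- min(n - 2L, max(10L, round(3 * trace$fs / cutoff)))
  xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
          2 * x[n] - rev(x[(n - np):(n - 1)]))
  yp <- as.numeric(signal::filtfilt(bf, xp))
  trace$size <- yp[(np + 1):(np + n)]
  trace
}

#' Downsample a pupil trace by an integer factor
#'
#' Decimation (every `fs / target_fs`-th sample) after low-pass filtering;
#' a downsampled sample is flagged interpolated/missing if any sample in
#' its source group was (any-masked rule). Events are unchanged (their
#' onsets stay in seconds).
#'
#' @param trace a `pupil_trace`.
#' @param target_fs target sampling rate, must divide `fs`.
#' @return the downsampled trace.
#' @export
downsample <- function(trace, target_fs = 250) {
  fac <- trace$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("target_fs must divide fs")
  fac <- as.integer(round(fac))
  n <- length(trace$size)
  grp <- ((seq_len(n) - 1L) %/% fac) + 1L
  keep <- seq(1L, n, by = fac)
  mask_any <- as.integer(tapply(trace$mask, grp, max))
  trace$size <- trace$size[keep]
  trace$time <- trace$time[keep]
  trace$mask <- mask_any[seq_along(keep)]
  trace$fs <- target_fs
  trace
}

#' Standard pupil preprocessing chain
#'
#' Blink detection, linear interpolation with margins, zero-phase low-pass,
#' and downsampling - the preprocessing applied before deconvolution.
#'
#' @param trace raw `pupil_trace`.
#' @param cutoff low-pass cutoff, Hz.
#' @param target_fs output sampling rate (NULL = keep; must divide fs).
#' @param k,margin,merge_distance blink-handling parameters.
#' @return preprocessed trace; blink table attached as `$blinks`.
#' @export
preprocess_pupil <- function(trace, cutoff = 5, target_fs = NULL,
                             k = 5, margin = 0.1, merge_distance = 0.2) {
  bl <- detect_blinks(trace, k = k, merge_distance = merge_distance)
  trace <- interpolate_blinks(trace, bl, margin = margin)
  trace <- lowpass(trace, cutoff)
  if (!is.null(target_fs) && target_fs != trace$fs)
    trace <- downsample(trace, target_fs)
  trace$blinks <- bl
  trace
}

# local minima of x with topographic prominence >= prom
find_troughs <- function(x, prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]; v <- x[i]
    # walk left/right until a lower value; prominence = min(max barrier)
    l <- i; lmax <- -Inf
    while (l > 1) { l <- l - 1; if (x[l] < v) break; lmax <- max(lmax, x[l]) }
    if (x[l] >= v) lmax <- max(lmax, x[l])
    r <- i; rmax <- -Inf
    while (r < n) { r <- r + 1; if (x[r] < v) break; rmax <- max(rmax, x[r]) }
    if (x[r] >= v) rmax <- max(rmax, x[r])
    keep[ci] <- (min(lmax, rmax) - v) >= prom
  }
  cand[keep]
}

#' Estimate the tonic (baseline) pupil component
#'
#' Two-pass estimate of the smooth baseline on which phasic responses
#' ride. Pass 1 detects high-prominence troughs in the preprocessed signal
#' - points where the signal returns to baseline between event responses -
#' and anchors a natural interpolating spline through them (a low-order
#' polynomial through the available minima when fewer than 4 troughs
#' exist, with a message). Pass 2 refines it by the joint decomposition:
#' the signal is modeled as a cubic B-spline baseline (knots every
#' `knot_spacing` seconds) plus non-negative PRF responses at the event
#' onsets, solved exactly by profiling the spline out of the non-negative
#' least-squares problem. The final curve is clipped so it never exceeds
#' the signal.
#'
#' @param trace preprocessed `pupil_trace`.
#' @param event_onsets task-event onsets (s) for the PRF model in pass 2;
#'   NULL fits the spline baseline to the signal alone.
#' @param prominence trough prominence threshold in signal units (default:
#'   0.25 * SD of the signal).
#' @param knot_spacing B-spline knot spacing in seconds (default 2).
#' @return list with `tonic` (same length as the trace), `trough_idx`,
#'   and `iterations`.
#' @export
estimate_tonic <- function(trace, event_onsets = NULL, prominence = NULL,
                           knot_spacing = 2) {
  x <- trace$size; tt <- trace$time
  if (anyNA(x)) stop("preprocess the trace first")
  if (is.null(prominence)) prominence <- 0.25 * stats::sd(x)

  # pass 1: trough-anchored natural spline (lower envelope)
  idx1 <- find_troughs(x, prominence)
  if (length(unique(idx1)) < 4) {
    message("fewer than 4 troughs: polynomial fallback for the trough pass")
    pts <- if (length(idx1) >= 2) idx1 else which.min(x)
    dg <- max(1, min(3, length(unique(pts)) - 1))
    if (length(unique(pts)) < 2) {
      tonic <- rep(x[pts[1]], length(x))
    } else {
      co <- stats::lm(x[pts] ~ poly(tt[pts], dg, raw = TRUE))
      tonic <- as.numeric(cbind(1, poly(tt, dg, raw = TRUE)) %*%
                            stats::coef(co))
    }
  } else {
    f <- stats::splinefun(tt[idx1], x[idx1], method = "natural")
    tonic <- f(tt)
    tonic[tt < tt[idx1[1]]] <- x[idx1[1]]
    tonic[tt > tt[idx1[length(idx1)]]] <- x[idx1[length(idx1)]]
  }
  iters <- 1L

  # pass 2: joint baseline + non-negative PRF decomposition
  span <- tt[length(tt)] - tt[1]
  if (span > 3 * knot_spacing) {
    knots <- seq(tt[1] + knot_spacing, tt[length(tt)] - knot_spacing,
                 by = knot_spacing)
    B <- cbind(1, splines::bs(tt, knots = knots))
    BtB <- crossprod(B)
    proj <- function(M) M - B %*% solve(BtB, crossprod(B, M))
    if (!is.null(event_onsets) && length(event_onsets)) {
      D <- prf_design(tt, event_onsets)
      b <- pracma::lsqnonneg(proj(D), as.numeric(proj(x)))$x
      gam <- solve(BtB, crossprod(B, x - D %*% b))
    } else {
      gam <- solve(BtB, crossprod(B, x))
    }
    tonic <- as.numeric(B %*% gam)
    iters <- 2L
  }
  tonic <- pmin(tonic, x)   # tonic stays below the signal
  list(tonic = tonic, trough_idx = idx1, iterations = iters)
}

# design matrix of shifted PRF kernels (rows = samples, cols = events)
prf_design <- function(times, event_onsets, n = 10, t_max = 900) {
  vapply(event_onsets,
         function(o) prf((times - o) * 1000, n = n, t_max = t_max),
         numeric(length(times)))
}

#' Estimate phasic response amplitudes by non-negative least squares
#'
#' Solves `min || (signal - tonic) - D b ||^2` subject to `b >= 0`, where
#' column j of `D` is the unit-peak PRF shifted to event onset j. Warns
#' when events are closer than 50 ms (near-collinear columns; downstream
#' code sums coefficients in a window rather than interpreting them
#' individually).
#'
#' @param trace preprocessed `pupil_trace`.
#' @param tonic tonic curve (same length as the trace).
#' @param event_onsets event onsets in seconds, within the trace span.
#' @return list with `coef` (non-negative, one per event), `fitted`
#'   (phasic model), `residual`.
#' @export
estimate_phasic <- function(trace, tonic, event_onsets) {
  tt <- trace$time
  if (any(event_onsets < tt[1] - 1e-9 | event_onsets > tt[length(tt)] + 1e-9))
    stop("event onsets outside trace span")
  if (any(diff(sort(event_onsets)) < 0.050))
    warning("events closer than 50 ms: coefficients are near-collinear")
  D <- prf_design(tt, event_onsets)
  y <- trace$size - tonic
  b <- pracma::lsqnonneg(D, y)$x
  fitted <- as.numeric(D %*% b)
  list(coef = b, fitted = fitted, residual = y - fitted)
}

#' Tonic/phasic decomposition of a preprocessed trace
#'
#' Convenience wrapper: [estimate_tonic()] then [estimate_phasic()].
#'
#' @param trace preprocessed `pupil_trace`.
#' @param event_onsets task-event onsets in seconds.
#' @param ... passed to [estimate_tonic()].
#' @return object of class `pupil_decomp`: `tonic`, `events` (data.frame
#'   `onset`, `coef`), `residual`, `trace`.
#' @export
pupil_decompose <- function(trace, event_onsets, ...) {
  tn <- estimate_tonic(trace, event_onsets, ...)
  ph <- estimate_phasic(trace, tn$tonic, event_onsets)
  out <- list(tonic = tn$tonic,
              events = data.frame(onset = event_onsets, coef = ph$coef),
              residual = ph$residual,
              trace = trace)
  class(out) <- "pupil_decomp"
  out
}

#' @export
print.pupil_decomp <- function(x, ...) {
  cat(sprintf("pupil decomposition: %d events, residual RMS %.3g\n",
              nrow(x$events), sqrt(mean(x$residual^2))))
  invisible(x)
}

#' Single-trial pupil features
#'
#' For every stimulus onset: the tonic value at the onset sample, the sum
#' of phasic coefficients from all events within `window` seconds before or
#' after the onset (the study's answer to stimulus/tap regressor
#' collinearity), and the fraction of interpolated/missing samples in the
#' trial span `[onset, onset + soa)`.
#'
#' @param decomp a [pupil_decompose()] result.
#' @param stim_onsets stimulus onsets in seconds.
#' @param soa trial duration in seconds (default 0.75).
#' @param window half-width of the coefficient-summing window, s
#'   (default 0.2).
#' @return data.frame `onset`, `tonic`, `phasic`, `missing_fraction`.
#' @export
trial_features <- function(decomp, stim_onsets, soa = 0.75, window = 0.2) {
  tr <- decomp$trace; tt <- tr$time
  if (any(stim_onsets < tt[1] - 1e-9 | stim_onsets > tt[length(tt)] + 1e-9))
    stop("stimulus onset outside trace")
  idx <- pmin(pmax(round((stim_onsets - tt[1]) * tr$fs) + 1L, 1L), length(tt))
  tonic <- decomp$tonic[idx]
  phasic <- vapply(stim_onsets, function(o)
    sum(decomp$events$coef[abs(decomp$events$onset - o) <= window + 1e-9]),
    numeric(1))
  miss <- vapply(stim_onsets, function(o) {
    sel <- tt >= o - 1e-9 & tt < o + soa - 1e-9
    if (!any(sel)) return(1)
    mean(tr$mask[sel] != 0L)
  }, numeric(1))
  data.frame(onset = stim_onsets, tonic = tonic, phasic = phasic,
             missing_fraction = miss)
}

#' Per-probe pupil features with the missing-data exclusion rule
#'
#' Averages single-trial tonic and phasic values over the `window` trials
#' preceding each probe (18.75 s for 25 trials at 750 ms SOA), ignoring
#' trials with more than `missing_max` missing pupil data. A probe whose
#' whole window is invalid is flagged excluded.
#'
#' @param trials data.frame from [trial_features()] (optionally z-scored),
#'   in trial order.
#' @param probe_trial_index index (into `trials`) of each probe's last
#'   preceding trial.
#' @param window trials per probe window (default 25).
#' @param missing_max maximum tolerated per-trial missing fraction
#'   (default 0.4).
#' @return data.frame `tonic`, `phasic`, `n_valid`, `excluded`.
#' @export
probe_pupil_features <- function(trials, probe_trial_index, window = 25L,
                                 missing_max = 0.4) {
  out <- lapply(probe_trial_index, function(k) {
    lo <- max(1L, k - window + 1L)
    w <- trials[lo:k, , drop = FALSE]
    valid <- w$missing_fraction <= missing_max
    if (!any(valid))
      return(data.frame(tonic = NA_real_, phasic = NA_real_,
                        n_valid = 0L, excluded = TRUE))
    data.frame(tonic = mean(w$tonic[valid]),
               phasic = mean(w$phasic[valid]),
               n_valid = sum(valid), excluded = FALSE)
  })
  do.call(rbind, out)
}

#' Attach per-probe pupil features to the behavioral probe table
#'
#' Fills the `tonic`/`phasic` columns of a [probe_features()] table and
#' marks probes excluded by the pupil missing-data rule.
#'
#' @param features a [probe_features()] table.
#' @param pupil_by_probe data.frame aligned with `features` rows, with
#'   `tonic`, `phasic`, `excluded` (from [probe_pupil_features()]).
#' @return the features table with pupil columns filled.
#' @export
add_pupil_features <- function(features, pupil_by_probe) {
  stopifnot(nrow(features) == nrow(pupil_by_probe))
  features$tonic <- pupil_by_probe$tonic
  features$phasic <- pupil_by_probe$phasic
  drop <- pupil_by_probe$excluded & !features$excluded
  features$excluded <- features$excluded | pupil_by_probe$excluded
  features$reason[drop] <- "more than 40% missing pupil data in all window trials"
  features
}
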