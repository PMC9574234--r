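#' Inter-tap intervals of a tap window
#'
#' @param times strictly increasing tap timestamps in seconds (>= 2).
#' @return consecutive differences, length `length(times) - 1`.
#' @examples
#' intertap_intervals(c(0, 0.75, 1.5))
#' @export
intertap_intervals <- function(times) {
  if (length(times) < 2) stop("need at least 2 taps")
  d <- diff(times)
  if (any(d <= 0)) stop("tap timestamps must be strictly increasing")
  d
}

#' Behavioral variability (BV) of a tap window
#'
#' BV is the sample standard deviation of the inter-tap intervals of the
#' taps in the window (by convention the `n - 1` intervals among `n` taps).
#' Because noiseless synthetic data can produce an exactly zero SD, the raw
#' SD is floored at `floor_s` (1 ms) before the log transform.
#'
#' @param times strictly increasing tap timestamps, seconds.
#' @param floor_s lower bound on the raw SD before taking the log.
#' @return list with `bv_raw` (s) and `bv_log` (`log(max(bv_raw, floor_s))`).
#' @examples
#' behavioral_variability(c(0, 0.7, 1.5, 2.2, 3.0))
#' @export
behavioral_variability <- function(times, floor_s = 1e-3) {
  iti <- intertap_intervals(times)
  bv_raw <- stats::sd(iti)
  list(bv_raw = bv_raw, bv_log = log(max(bv_raw, floor_s)))
}

#' Approximate entropy of a binary response sequence
#'
#' Quantifies sequence regularity as `AE = Phi_m - Phi_(m+1)` with
#' `Phi_k = (N - m)^-1 * sum_i log(C_i^k)` where `C_i^k` is the fraction of
#' length-`k` windows exactly matching window `i` (self-matches included;
#' exact symbol matching, the natural convention for discrete binary
#' sequences where a tolerance radius is meaningless). Both sums run over
#' the common index set `i = 1 .. N - m` - the positions whose length-`m`
#' template has a continuation - so AE equals the average conditional
#' log-probability `-mean(log(A_i / B_i))` of the next symbol given the
#' template. On a binary alphabet this puts AE in `[0, log(2)]` exactly:
#' 0 for perfectly regular sequences (constant or strictly alternating,
#' which are completely predictable), `log(2)` in the iid fair-coin limit.
#'
#' @param seq a binary sequence: factor/character with 2 symbols (e.g.
#'   "L"/"R") or integer/logical.
#' @param m template length (default 2, as used for the FT-RSGT).
#' @return approximate entropy in nats.
#' @examples
#' approximate_entropy(rep(c("L", "R"), length.out = 25))  # 0
#' @export
approximate_entropy <- function(seq, m = 2L) {
  x <- .as_binary(seq)
  n <- length(x)
  m <- as.integer(m)
  if (m < 1) stop("m must be at least 1")
  if (n < m + 1) stop("sequence shorter than m + 1")
  nw <- n - m                      # windows with a continuation
  code_of <- function(k) {
    code <- 0L
    for (j in 0:(k - 1L)) code <- code * 2L + x[(1L + j):(nw + j)]
    code
  }
  cm <- code_of(m)
  cm1 <- code_of(m + 1L)
  B <- tabulate(cm + 1L, nbins = 2L^m)[cm + 1L]
  A <- tabulate(cm1 + 1L, nbins = 2L^(m + 1L))[cm1 + 1L]
  mean(log(B / A))
}

.as_binary <- function(seq) {
  if (is.logical(seq)) return(as.integer(seq))
  if (is.factor(seq)) seq <- as.character(seq)
  u <- unique(seq)
  if (length(u) > 2) stop("sequence is not binary")
  if (is.character(seq)) return(as.integer(seq == sort(u)[1]))
  u <- sort(unique(as.integer(seq)))
  if (!all(as.integer(seq) %in% u) || length(u) > 2)
    stop("sequence is not binary")
  as.integer(as.integer(seq) == u[1])
}

#' Variance-stabilizing transform of approximate entropy
#'
#' `-log(log(2) - AE)`, strictly increasing on `[0, log(2))`; AE values at
#' (or within `eps` of) the `log(2)` singularity are capped at
#' `log(2) - eps` first.
#'
#' @param ae approximate entropy in nats, within `[0, log(2)]`.
#' @param eps singularity guard (default 1e-6).
#' @return transformed value(s).
#' @examples
#' transform_ae(0)  # -log(log(2)) ~ 0.3665
#' @export
transform_ae <- function(ae, eps = 1e-6) {
  if (any(ae < -1e-12 | ae > log(2) + 1e-12))
    stop("ae outside [0, log(2)]")
  -log(log(2) - pmin(ae, log(2) - eps))
}

#' Grand (across-subject) z-scoring
#'
#' Standardizes pooled values by the grand mean and grand SD, the study's
#' convention for BV and AE.
#'
#' @param x numeric vector (NAs ignored for the moments, preserved in the
#'   output).
#' @return z-scored vector.
#' @export
zscore_grand <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Within-subject z-scoring of feature columns
#'
#' @param df data.frame containing `subject` plus the columns to scale.
#' @param cols character vector of column names to z-score within subject.
#' @return df with the named columns standardized per subject.
#' @export
zscore_within_subject <- function(df, cols) {
  for (cl in cols) {
    df[[cl]] <- stats::ave(df[[cl]], df$subject, FUN = function(v) {
      s <- stats::sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score")
      (v - mean(v, na.rm = TRUE)) / s
    })
  }
  df
}

#' Sliding single-trial BV/AE series for one block
#'
#' Starting at the 25th metronome onset of the block, BV (and AE for random
#' blocks) is computed for every trial from the preceding `window` recorded
#' taps. "Preceding" includes the current trial's own response: the window
#' at stimulus k uses the last `window` taps occurring before `onset_k +
#' soa`, so with one tap per stimulus the series has `n_stimuli - window +
#' 1` entries. The raw tap stream is used as recorded - extra (double) and
#' missing taps shift windows rather than being filtered out.
#'
#' @param taps data.frame with `time` and `hand` (raw stream, sorted).
#' @param stim_onsets stimulus onsets of the block, seconds.
#' @param soa stimulus-onset asynchrony, seconds.
#' @param condition "random" or "alternating" (AE computed only for random).
#' @param window taps per window (default 25).
#' @return data.frame `trial`, `onset`, `bv_raw`, `bv_log`, `ae_raw`, `ae`
#'   (transformed); AE columns are NA for alternating blocks. Zero rows if
#'   the block is shorter than the window.
#' @export
sliding_markers <- function(taps, stim_onsets, soa, condition = "random",
                            window = 25L) {
  n <- length(stim_onsets)
  if (n < window || nrow(taps) < window)
    return(data.frame(trial = integer(0), onset = numeric(0),
                      bv_raw = numeric(0), bv_log = numeric(0),
                      ae_raw = numeric(0), ae = numeric(0)))
  trials <- window:n
  out <- lapply(trials, function(k) {
    upto <- stim_onsets[k] + soa
    idx <- which(taps$time < upto)
    if (length(idx) < window)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    sel <- idx[(length(idx) - window + 1L):length(idx)]
    w_times <- taps$time[sel]
    if (any(diff(w_times) <= 0))
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    bv <- behavioral_variability(w_times)
    if (condition == "random") {
      ae <- approximate_entropy(taps$hand[sel])
      c(bv$bv_raw, bv$bv_log, ae, transform_ae(ae))
    } else c(bv$bv_raw, bv$bv_log, NA_real_, NA_real_)
  })
  out <- do.call(rbind, out)
  data.frame(trial = trials, onset = stim_onsets[trials],
             bv_raw = out[, 1], bv_log = out[, 2],
             ae_raw = out[, 3], ae = out[, 4])
}

#' Per-probe behavioral feature table
#'
#' One row per thought probe with the time covariate (probe number), the
#' probe response, and BV/AE computed from the `window` taps immediately
#' preceding the probe onset. AE is computed for random blocks only.
#' Probes with fewer than `window` preceding taps are flagged excluded.
#' `bv` and `ae` are grand-z-scored (log/transformed scale) across all
#' included rows of the cohort; `tonic`/`phasic` are left NA for
#' [add_pupil_features()] to fill.
#'
#' @param session an `ftrsgt_session` from [simulate_session()], or a list
#'   with the same `subjects` structure built from read-in data.
#' @param window taps per probe window (default 25).
#' @return data.frame with columns `subject`, `probe_index`, `block`,
#'   `condition`, `response`, `bv_raw`, `bv_log`, `bv`, `ae_raw`, `ae`,
#'   `tonic`, `phasic`, `excluded`, `reason`.
#' @export
probe_features <- function(session, window = 25L) {
  rows <- list()
  for (sub in session$subjects) {
    taps <- sub$taps
    for (i in seq_len(nrow(sub$probes))) {
      pr <- sub$probes[i, ]
      idx <- which(taps$time < pr$probe_onset & taps$block == pr$block)
      excluded <- FALSE; reason <- NA_character_
      bv_raw <- bv_log <- ae_raw <- ae_t <- NA_real_
      if (length(idx) < window) {
        excluded <- TRUE; reason <- "fewer than window taps before probe"
      } else {
        sel <- idx[(length(idx) - window + 1L):length(idx)]
        bv <- behavioral_variability(taps$time[sel])
        bv_raw <- bv$bv_raw; bv_log <- bv$bv_log
        if (pr$condition == "random") {
          ae_raw <- approximate_entropy(taps$hand[sel])
          ae_t <- transform_ae(ae_raw)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub$subject, probe_index = pr$probe_index,
        block = pr$block, condition = pr$condition,
        response = pr$response, bv_raw = bv_raw, bv_log = bv_log,
        ae_raw = ae_raw, ae = ae_t,
        excluded = excluded, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ok <- !out$excluded
  out$bv <- NA_real_
  out$bv[ok] <- zscore_grand(out$bv_log[ok])
  ok_ae <- ok & !is.na(out$ae)
  if (any(ok_ae)) out$ae[ok_ae] <- zscore_grand(out$ae[ok_ae])
  out$tonic <- NA_real_
  out$phasic <- NA_real_
  out[c("subject", "probe_index", "block", "condition", "response",
        "bv_raw", "bv_log", "bv", "ae_raw", "ae", "tonic", "phasic",
        "excluded", "reason")]
}

#' Subject-specific split-point dichotomization of probe responses
#'
#' Chooses, per subject, the cutpoint in `1..5` for which labeling
#' responses above it "off-task" brings the off-task proportion closest to
#' 50%; ties are broken toward the smaller cutpoint (more off-task).
#'
#' @param responses integer responses in 1..6 for one subject.
#' @return list with `cutpoint`, `off_task` (logical labels) and
#'   `proportion` (achieved off-task proportion).
#' @examples
#' split_point_dichotomize(c(1, 1, 2, 2))$cutpoint  # 1
#' @export
split_point_dichotomize <- function(responses) {
  if (length(responses) < 1) stop("need at least one response")
  if (!all(responses %in% 1:6)) stop("responses must be in 1..6")
  props <- vapply(1:5, function(cut) mean(responses > cut), numeric(1))
  cutpoint <- which.min(abs(props - 0.5))   # which.min takes the first tie
  list(cutpoint = cutpoint,
       off_task = responses > cutpoint,
       proportion = props[cutpoint])
}

#' Fixed-boundary dichotomization
#'
#' Collapses categories 1-3 into on-task and 4-6 into off-task.
#'
#' @param responses integer responses in 1..6.
#' @return logical vector, TRUE = off-task.
#' @export
fixed_dichotomize <- function(responses) {
  if (!all(responses %in% 1:6)) stop("responses must be in 1..6")
  responses >= 4
}
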