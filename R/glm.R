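#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities - a positive response peaking at
#' `peak` seconds minus an undershoot peaking at `undershoot` seconds,
#' weighted by `ratio` - rescaled to unit peak.
#'
#' @param t time in seconds (>= 0; negative times map to 0).
#' @param peak response peak latency, s (default 6).
#' @param undershoot undershoot peak latency, s (default 16).
#' @param ratio undershoot weight (default 1/6).
#' @return kernel values, maximum 1.
#' @export
double_gamma_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  if (peak <= 0 || undershoot <= 0 || ratio < 0)
    stop("invalid HRF shape parameters")
  g <- function(x, mode) stats::dgamma(x, shape = mode + 1, rate = 1)
  raw <- function(x) g(x, peak) - ratio * g(x, undershoot)
  grid <- seq(0, undershoot + 16, by = 0.01)
  pk <- max(raw(grid))
  out <- ifelse(t < 0, 0, raw(t) / pk)
  out
}

#' Convolve event onsets into an fMRI regressor column
#'
#' Builds a stick (zero-duration) or boxcar function on a fine grid,
#' convolves it with the HRF, and samples the result at volume acquisition
#' times `0, tr, 2 tr, ...`.
#'
#' @param onsets event onsets, seconds.
#' @param durations per-event durations, seconds (0 = stick); recycled.
#' @param tr repetition time, seconds.
#' @param n_volumes number of volumes.
#' @param amplitudes per-event amplitudes (default 1); recycled.
#' @param hrf kernel function of time in seconds.
#' @param dt high-resolution grid step; must divide `tr` (default
#'   `tr / 36` = 0.05 s for TR 1.8).
#' @return numeric regressor of length `n_volumes`. Events at or beyond
#'   the scan end are dropped with a warning.
#' @export
events_to_regressor <- function(onsets, durations = 0, tr, n_volumes,
                                amplitudes = 1, hrf = double_gamma_hrf,
                                dt = tr / 36) {
  scan_len <- n_volumes * tr
  if (length(onsets) == 0) return(numeric(n_volumes))
  durations <- rep_len(durations, length(onsets))
  amplitudes <- rep_len(amplitudes, length(onsets))
  drop <- onsets >= scan_len
  if (any(drop)) {
    warning(sprintf("%d event(s) beyond scan end dropped", sum(drop)))
    onsets <- onsets[!drop]; durations <- durations[!drop]
    amplitudes <- amplitudes[!drop]
    if (!length(onsets)) return(numeric(n_volumes))
  }
  n_hi <- ceiling(scan_len / dt)
  x <- numeric(n_hi)
  for (j in seq_along(onsets)) {
    i1 <- floor(onsets[j] / dt) + 1L
    i2 <- if (durations[j] > 0)
      min(n_hi, ceiling((onsets[j] + durations[j]) / dt)) else i1
    x[i1:i2] <- x[i1:i2] + amplitudes[j]
  }
  k <- hrf(seq(0, 48, by = dt))
  conv <- stats::convolve(x, rev(k), type = "open")[seq_len(n_hi)]
  vol_idx <- round((0:(n_volumes - 1)) * tr / dt) + 1L
  conv[pmin(vol_idx, n_hi)]
}

#' Pre-probe boxcar regressors for off-task versus on-task probes
#'
#' Models the `interval` seconds preceding each thought probe with a
#' boxcar, split by the dichotomized probe label, and convolves with the
#' HRF. Boxcars are truncated at the block start where needed.
#'
#' @param probe_onsets probe onsets, seconds.
#' @param off_task logical labels (from [split_point_dichotomize()] or
#'   [fixed_dichotomize()]).
#' @param tr,n_volumes scan timing.
#' @param interval boxcar length in seconds (default 10; 18 for the
#'   sensitivity variant).
#' @param block_starts optional block start times used for truncation.
#' @param ... passed to [events_to_regressor()].
#' @return matrix with columns `off_task`, `on_task`.
#' @export
preprobe_boxcars <- function(probe_onsets, off_task, tr, n_volumes,
                             interval = 10, block_starts = NULL, ...) {
  stopifnot(length(probe_onsets) == length(off_task))
  starts <- probe_onsets - interval
  if (!is.null(block_starts)) {
    bs <- vapply(probe_onsets, function(p) {
      cand <- block_starts[block_starts <= p]
      if (length(cand)) max(cand) else 0
    }, numeric(1))
    starts <- pmax(starts, bs)
  } else starts <- pmax(starts, 0)
  durs <- probe_onsets - starts
  col <- function(sel) {
    if (!any(sel)) return(numeric(n_volumes))
    events_to_regressor(starts[sel], durs[sel], tr, n_volumes, ...)
  }
  cbind(off_task = col(off_task), on_task = col(!off_task))
}

#' Sliding-marker or pupil regressor column
#'
#' `mode = "nearest"` (BV, AE, tonic): the marker series is held at the
#' nearest anchor and sampled at volume times without convolution - the
#' 25-tap sliding window already yields a smooth, time-lagged signal.
#' Volumes before the first anchor take the first value. `mode =
#' "convolve"` (phasic): anchors become amplitude-weighted sticks
#' convolved with the HRF. `mode = "linear"` is provided as a variant for
#' sensitivity analyses.
#'
#' @param anchor_times anchor (trial) times, seconds, sorted.
#' @param values marker values at the anchors.
#' @param tr,n_volumes scan timing.
#' @param mode `"nearest"`, `"linear"` or `"convolve"`.
#' @param ... passed to [events_to_regressor()] for `"convolve"`.
#' @return numeric regressor of length `n_volumes`.
#' @export
marker_regressor <- function(anchor_times, values, tr, n_volumes,
                             mode = c("nearest", "linear", "convolve"),
                             ...) {
  mode <- match.arg(mode)
  if (!length(anchor_times)) stop("empty marker series")
  stopifnot(length(anchor_times) == length(values))
  vol_t <- (0:(n_volumes - 1)) * tr
  if (mode == "convolve")
    return(events_to_regressor(anchor_times, 0, tr, n_volumes,
                               amplitudes = values, ...))
  method <- if (mode == "nearest") "constant" else "linear"
  if (mode == "nearest") {
    # nearest anchor (not last-carried-forward): switch at midpoints
    idx <- vapply(vol_t, function(tv)
      which.min(abs(anchor_times - tv)), integer(1))
    return(values[idx])
  }
  stats::approx(anchor_times, values, xout = vol_t, rule = 2)$y
}

#' Discrete-cosine drift basis
#'
#' Orthonormal DCT-II columns with periods longer than `cutoff_s`,
#' modeling low-frequency scanner drift.
#'
#' @param n_volumes number of volumes.
#' @param tr repetition time, seconds.
#' @param cutoff_s high-pass cutoff period, seconds (default 128).
#' @return matrix `n_volumes x K` (possibly 0 columns).
#' @export
dct_basis <- function(n_volumes, tr, cutoff_s = 128) {
  K <- floor(2 * n_volumes * tr / cutoff_s)
  if (K < 1) return(matrix(0, n_volumes, 0))
  t_idx <- 0:(n_volumes - 1)
  cols <- vapply(seq_len(K), function(k)
    sqrt(2 / n_volumes) * cos(pi * (2 * t_idx + 1) * k / (2 * n_volumes)),
    numeric(n_volumes))
  colnames(cols) <- paste0("dct", seq_len(K))
  cols
}

#' Simulated nuisance regressors (CSF, WM, FD, motion)
#'
#' Smooth random walks standing in for the image-derived nuisance series;
#' real extraction from volumes is out of scope for this pipeline.
#'
#' @param n_volumes number of volumes.
#' @param seed integer seed.
#' @return matrix with columns `csf`, `wm`, `fd`, `mot1`..`mot6`.
#' @export
nuisance_regressors <- function(n_volumes, seed = 1L) {
  set.seed(seed)
  smooth_walk <- function() {
    x <- cumsum(stats::rnorm(n_volumes, 0, 0.1))
    as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2, circular = TRUE))
  }
  m <- vapply(seq_len(9), function(i) smooth_walk(), numeric(n_volumes))
  m[, 3] <- abs(m[, 3])   # framewise displacement is non-negative
  colnames(m) <- c("csf", "wm", "fd", paste0("mot", 1:6))
  m
}

#' Mass-univariate OLS GLM with a contrast z-map
#'
#' Per-voxel ordinary least squares; the contrast t statistic (with
#' `n - p` degrees of freedom) is mapped to a z statistic through the
#' normal quantile transform.
#'
#' @param Y 4D array (x, y, z, time) or matrix (voxels x time).
#' @param X design matrix, volumes x regressors.
#' @param contrast numeric contrast vector of length `ncol(X)`.
#' @return object of class `contrast_map`: `beta` (array or matrix),
#'   `zmap`, `tmap`, `df`, `dims`.
#' @export
fit_glm <- function(Y, X, contrast) {
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning(sprintf("design matrix rank deficient (rank %d < %d columns): %s",
                    qx$rank, ncol(X),
                    paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]],
                          collapse = ", ")))
  dims <- NULL
  if (is.array(Y) && length(dim(Y)) == 4) {
    dims <- dim(Y)[1:3]
    Y <- matrix(Y, nrow = prod(dims))      # voxels x time
  }
  Ym <- t(Y)                               # time x voxels
  n <- nrow(Ym); p <- ncol(X); df <- n - p
  XtX <- crossprod(X)
  XtXinv <- tryCatch(chol2inv(chol(XtX)),
                     error = function(e) pracma::pinv(XtX))
  beta <- XtXinv %*% crossprod(X, Ym)      # p x voxels
  res <- Ym - X %*% beta
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  se <- sqrt(sigma2 * cvar)
  tstat <- drop(t(contrast) %*% beta) / se
  tstat[se == 0] <- 0
  # tail-stable t -> z conversion
  z <- ifelse(tstat >= 0,
              stats::qnorm(stats::pt(tstat, df, lower.tail = FALSE),
                           lower.tail = FALSE),
              stats::qnorm(stats::pt(tstat, df)))
  out <- list(beta = if (is.null(dims)) beta else
                array(t(beta), dim = c(dims, p)),
              tmap = if (is.null(dims)) tstat else array(tstat, dim = dims),
              zmap = if (is.null(dims)) z else array(z, dim = dims),
              df = df, dims = dims)
  class(out) <- "contrast_map"
  out
}

#' Threshold a z-map into 26-connected clusters
#'
#' Voxels with `z > z_primary` are labeled into 26-connected components;
#' components smaller than `min_cluster` voxels are removed. Cluster-level
#' Gaussian-random-field p-values are deliberately not computed; the
#' minimum-cluster-size rule substitutes for them, and the metadata
#' records this deviation.
#'
#' @param zmap 3D z-statistic array.
#' @param z_primary primary voxel-level threshold (default 2.3).
#' @param min_cluster minimum cluster size in voxels (default 1).
#' @return list of class `thresholded_map`: `mask` (logical array),
#'   `labels` (integer array, 0 = background), `sizes` (per-cluster voxel
#'   counts), `meta`.
#' @export
threshold_map <- function(zmap, z_primary = 2.3, min_cluster = 1L) {
  if (!all(is.finite(zmap))) stop("zmap must be finite")
  mask <- zmap > z_primary
  lab <- label_components(mask)
  sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  small <- which(sizes < min_cluster)
  if (length(small)) {
    lab[lab %in% small] <- 0L
    mask <- lab > 0L
    keep <- setdiff(seq_along(sizes), small)
    relab <- integer(length(sizes)); relab[keep] <- seq_along(keep)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    sizes <- sizes[keep]
  }
  out <- list(mask = mask, labels = lab, sizes = sizes,
              meta = list(z_primary = z_primary, min_cluster = min_cluster,
                          connectivity = 26,
                          note = paste("cluster extent rule; GRF cluster-level",
                                       "p-values not computed")))
  class(out) <- "thresholded_map"
  out
}

#' Label 26-connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be 3D")
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]          # 26 neighbors
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  coord <- arrayInd(idx_all, d)
  key <- function(co) (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
  current <- 0L
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      co <- arrayInd(v, d)
      cand <- cbind(co[1] + nbr[, 1], co[2] + nbr[, 2], co[3] + nbr[, 3])
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      ci <- key(cand)
      sel <- mask[ci] & lab[ci] == 0L
      if (any(sel)) {
        lab[ci[sel]] <- current
        queue <- c(queue, ci[sel])
      }
    }
  }
  lab
}

#' Atlas-overlap percentages of a thresholded map
#'
#' Distributes the suprathreshold voxels (after removing those in the
#' white-matter mask) over a list of binarized parcellations. Voxels are
#' assigned to the first parcel containing them, so on a full-cover
#' parcellation the percentages sum to exactly 100. Voxels covered by no
#' parcel violate the full-cover contract and raise an error unless
#' `allow_unassigned` is TRUE, in which case an `unassigned` row is
#' reported.
#'
#' @param thr a `thresholded_map` (or logical 3D array).
#' @param parcels named list of logical/0-1 3D arrays on the same grid.
#' @param wm_mask optional logical array: suprathreshold voxels inside it
#'   are ignored.
#' @param allow_unassigned report rather than fail on uncovered voxels.
#' @return data.frame `parcel`, `n_voxels`, `percent`.
#' @export
atlas_overlap <- function(thr, parcels, wm_mask = NULL,
                          allow_unassigned = FALSE) {
  mask <- if (inherits(thr, "thresholded_map")) thr$mask else thr
  vox <- which(mask)
  if (!is.null(wm_mask)) vox <- setdiff(vox, which(as.logical(wm_mask)))
  n <- length(vox)
  counts <- integer(length(parcels))
  names(counts) <- names(parcels)
  remaining <- vox
  for (i in seq_along(parcels)) {
    inp <- intersect(remaining, which(as.logical(parcels[[i]])))
    counts[i] <- length(inp)
    remaining <- setdiff(remaining, inp)
  }
  if (length(remaining) && !allow_unassigned)
    stop(sprintf("%d suprathreshold voxel(s) not covered by any parcel",
                 length(remaining)))
  tab <- data.frame(parcel = names(parcels), n_voxels = as.integer(counts),
                    percent = if (n) 100 * counts / n else rep(0, length(counts)),
                    stringsAsFactors = FALSE)
  if (length(remaining))
    tab <- rbind(tab, data.frame(parcel = "unassigned",
                                 n_voxels = length(remaining),
                                 percent = 100 * length(remaining) / n))
  rownames(tab) <- NULL
  tab
}

#' Dice similarity coefficient of two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty maps give 0 with a
#' warning.
#'
#' @param a,b logical arrays on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' dice(array(c(TRUE, TRUE, FALSE), c(3, 1, 1)),
#'      array(c(TRUE, FALSE, TRUE), c(3, 1, 1)))
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("maps must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both maps empty: Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / (na + nb)
}
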