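# Independent brute-force approximate-entropy oracle: counts exact window
# matches by direct comparison of window keys, over the common index set of
# templates that have a continuation.
ae_bruteforce <- function(x01, m = 2L) {
  n <- length(x01)
  stopifnot(n >= m + 1)
  nw <- n - m
  win_keys <- function(k) {
    vapply(seq_len(nw), function(i) paste(x01[i:(i + k - 1L)], collapse = ""),
           character(1))
  }
  km <- win_keys(m)
  km1 <- win_keys(m + 1L)
  B <- vapply(km, function(kk) sum(km == kk), numeric(1))
  A <- vapply(km1, function(kk) sum(km1 == kk), numeric(1))
  mean(log(B / A))
}

# all binary sequences of length n as rows of a matrix
all_binary <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

# bare pupil trace constructor for fixtures
make_trace <- function(size, fs, events = NULL) {
  structure(list(time = (seq_along(size) - 1) / fs, size = size, fs = fs,
                 mask = ifelse(is.na(size), 2L, 0L), events = events),
            class = "pupil_trace")
}

# simulate an ordered-probit dataset at study scale
make_probit_sim <- function(n_sub = 27, n_probe = 18,
                            beta = c(0.09, 0.33, -0.09, 0.07),
                            cutpoints = seq(-2, 2, 1), sigma_u = 0.5,
                            seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(n_sub), each = n_probe)
  time_z <- rep(as.numeric(scale(seq_len(n_probe))), n_sub)
  bv <- stats::rnorm(n_sub * n_probe)
  ae <- stats::rnorm(n_sub * n_probe)
  u <- stats::rnorm(n_sub, 0, sigma_u)
  X <- cbind(time = time_z, bv = bv, ae = ae, bvae = bv * ae)
  y <- simulate_probe_response(X, beta, cutpoints, u = u[subj],
                               seed = seed + 1)
  data.frame(response = y, time = time_z, bv = bv, ae = ae, subject = subj)
}
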