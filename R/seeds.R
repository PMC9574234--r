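#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single integer seed. Stage-,
#' subject- and block-level seeds are derived with a fixed
#' multiplicative-congruential hash so that any component of a simulated
#' session can be regenerated in isolation, bit-identically, from the master
#' seed plus its integer coordinates.
#'
#' The scheme is `s <- seed mod (2^31 - 1)` followed, for each coordinate
#' `k`, by `s <- (69069 * s + 9973 * k + 1) mod (2^31 - 1)`. Coordinates are
#' small non-negative integers (stage code, subject index, block index).
#'
#' @param seed master integer seed.
#' @param ... integer coordinates identifying the stream (stage, subject,
#'   block, ...).
#' @return a single integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' split_seed(1, 2, 3)
#' @export
split_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  s <- as.double(seed) %% m
  for (k in c(...)) {
    s <- (69069 * s + 9973 * as.double(k) + 1) %% m
  }
  as.integer(s)
}

# stage codes used by the generator (documented for reproducibility)
.stage <- c(blocks = 1L, latent = 2L, taps = 3L, probes = 4L,
            pupil = 5L, bold = 6L, nuisance = 7L)
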