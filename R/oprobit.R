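#' Weakly informative priors for the hierarchical ordered probit
#'
#' Normal(0, 2.5) coefficients, ordered Student-t(3, 0, 2.5) cutpoints and
#' half-Student-t(3, 0, 2.5) on the subject-intercept SD, mirroring common
#' Bayesian regression defaults.
#'
#' @param beta_scale SD of the Normal prior on coefficients.
#' @param cut_df,cut_scale Student-t prior on cutpoints.
#' @param sigma_df,sigma_scale half-Student-t prior on `sigma_u`.
#' @return list of prior settings.
#' @export
oprobit_prior <- function(beta_scale = 2.5, cut_df = 3, cut_scale = 2.5,
                          sigma_df = 3, sigma_scale = 2.5) {
  list(beta_scale = beta_scale, cut_df = cut_df, cut_scale = cut_scale,
       sigma_df = sigma_df, sigma_scale = sigma_scale)
}

#' Log-likelihood of the hierarchical ordered probit
#'
#' `sum_i log[Phi(c_{y_i} - eta_i) - Phi(c_{y_i - 1} - eta_i)]` with
#' `eta = X beta + u[subject]`, `c_0 = -Inf`, `c_K = +Inf`, plus the
#' `Normal(0, sigma_u)` density of the subject intercepts when
#' `include_ranef_density` is TRUE. Non-monotone cutpoints yield `-Inf`
#' (a rejected state).
#'
#' @param y integer responses in `1..K`.
#' @param X design matrix (no intercept; the cutpoints absorb it).
#' @param subject integer subject index (1-based) per row.
#' @param beta coefficient vector.
#' @param cutpoints cutpoint vector, length `K - 1`.
#' @param u subject intercepts (one per subject).
#' @param sigma_u subject-intercept SD (> 0).
#' @param K number of response categories.
#' @param include_ranef_density add `sum(dnorm(u, 0, sigma_u, log = TRUE))`.
#' @return log density (scalar).
#' @export
ordered_probit_loglik <- function(y, X, subject, beta, cutpoints, u,
                                  sigma_u = 1, K = max(y),
                                  include_ranef_density = TRUE) {
  if (any(diff(cutpoints) <= 0) || sigma_u <= 0) return(-Inf)
  eta <- drop(as.matrix(X) %*% beta) + u[subject]
  lo <- c(-Inf, cutpoints)[y]
  hi <- c(cutpoints, Inf)[y]
  p <- stats::pnorm(hi - eta) - stats::pnorm(lo - eta)
  ll <- sum(log(pmax(p, 1e-300)))
  if (include_ranef_density)
    ll <- ll + sum(stats::dnorm(u, 0, sigma_u, log = TRUE))
  ll
}

# categorical log-likelihood given a fixed linear predictor
.cat_loglik <- function(y, eta, cutpoints) {
  lo <- c(-Inf, cutpoints)[y]
  hi <- c(cutpoints, Inf)[y]
  p <- stats::pnorm(hi - eta) - stats::pnorm(lo - eta)
  sum(log(pmax(p, 1e-300)))
}

.halft_logprior <- function(sigma, df, scale) {
  stats::dt(sigma / scale, df = df, log = TRUE) - log(scale) + log(2)
}

#' Fit a Bayesian hierarchical ordered probit model
#'
#' Ordinal responses `1..K` are modeled through a latent normal variable
#' `y* = X beta + u[subject] + eps`, `eps ~ N(0, 1)`, partitioned by
#' `K - 1` ordered cutpoints; subjects contribute random intercepts
#' `u_s ~ N(0, sigma_u^2)`. Posterior draws come from a blocked MCMC
#' sampler: Albert-Chib latent-variable augmentation gives conjugate
#' updates for `beta` and `u`, while the cutpoints (on an unconstrained
#' log-difference scale) and `log(sigma_u)` get adaptive random-walk
#' Metropolis updates against the marginal categorical likelihood.
#' Defaults follow the study's sampler settings: 4 chains, 1000 warm-up
#' and 4000 post-warm-up draws each. Split-Rhat and effective sample sizes
#' are attached; fits with Rhat >= 1.01 are flagged unreliable.
#'
#' @param formula model formula, e.g. `response ~ time + bv + ae + bv:ae`.
#'   The intercept is always dropped (the cutpoints absorb it).
#' @param data data.frame holding the response, covariates and the subject
#'   column.
#' @param subject name of the subject-identifier column (default
#'   `"subject"`).
#' @param K number of response categories (default: max response).
#' @param prior an [oprobit_prior()].
#' @param chains number of chains (default 4).
#' @param warmup warm-up (adaptation) iterations per chain (default 1000).
#' @param iter post-warm-up iterations per chain (default 4000).
#' @param seed integer seed; fits are deterministic given it.
#' @return object of class `oprobit_fit`: `draws` (matrix, rows =
#'   retained draws across chains; columns = coefficients, cutpoints,
#'   `sigma_u`, subject intercepts), `chain` index per draw, `diagnostics`
#'   (Rhat/ESS per parameter), `X`, `y`, `subject`, `terms`, `call`.
#' @examples
#' d <- data.frame(response = sample(1:6, 60, TRUE), x = rnorm(60),
#'                 subject = rep(1:6, each = 10))
#' fit <- oprobit_hier(response ~ x, d, chains = 2, warmup = 50, iter = 100)
#' coef(fit)
#' @export
oprobit_hier <- function(formula, data, subject = "subject", K = NULL,
                         prior = oprobit_prior(), chains = 4,
                         warmup = 1000, iter = 4000, seed = 1L) {
  stopifnot(chains >= 1, warmup >= 10, iter >= 10)
  mf <- stats::model.frame(formula, data)
  y <- as.integer(stats::model.response(mf))
  if (is.null(K)) K <- max(y)
  if (K < 2 || any(y < 1 | y > K)) stop("responses must be integers in 1..K")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!subject %in% names(data)) stop("subject column not found")
  if (nrow(mf) != nrow(data))
    stop("missing values in model variables: drop excluded rows first")
  subj <- as.integer(factor(data[[subject]]))
  if (anyNA(cbind(X, y, subj))) stop("missing values in included rows")
  n <- length(y); p <- ncol(X); S <- max(subj)

  XtX <- crossprod(X)
  A <- XtX + diag(1 / prior$beta_scale^2, p)
  cA <- chol(A)
  ns <- tabulate(subj, S)
  n_par <- p + (K - 1) + 1 + S
  parnames <- c(colnames(X), paste0("cut", 1:(K - 1)), "sigma_u",
                paste0("u[", 1:S, "]"))

  emp <- cumsum(tabulate(y, K))[1:(K - 1)] / n
  cut0 <- stats::qnorm(pmin(pmax(emp, 0.01), 0.99))
  cut0 <- cut0 + cumsum(c(0, pmax(0, 1e-3 - diff(cut0))))  # enforce order

  cat_rows <- lapply(seq_len(K), function(k) which(y == k))

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    beta <- rep(0, p); u <- rep(0, S); sigma_u <- 1
    cuts <- cut0
    s_cut <- rep(0.2, K - 1); s_ls <- 0.3; s_sh <- 0.2
    total <- warmup + iter
    out <- matrix(NA_real_, iter, n_par)
    # cutpoint k enters the likelihood only through rows with y in {k, k+1}
    ll_cut <- function(k, val, cuts, eta) {
      ik <- cat_rows[[k]]; ik1 <- cat_rows[[k + 1]]
      lo_k <- if (k == 1) -Inf else cuts[k - 1]
      hi_k <- if (k == K - 1) Inf else cuts[k + 1]
      ll <- 0
      if (length(ik))
        ll <- ll + sum(log(pmax(stats::pnorm(val - eta[ik]) -
                                  stats::pnorm(lo_k - eta[ik]), 1e-300)))
      if (length(ik1))
        ll <- ll + sum(log(pmax(stats::pnorm(hi_k - eta[ik1]) -
                                  stats::pnorm(val - eta[ik1]), 1e-300)))
      ll + stats::dt(val / prior$cut_scale, df = prior$cut_df, log = TRUE)
    }
    for (it in seq_len(total)) {
      eta <- drop(X %*% beta) + u[subj]
      ## cutpoints: coordinate-wise Metropolis within the bracketing
      ## interval, against the marginal categorical likelihood
      for (k in seq_len(K - 1)) {
        lo_k <- if (k == 1) -Inf else cuts[k - 1]
        hi_k <- if (k == K - 1) Inf else cuts[k + 1]
        prop <- cuts[k] + stats::rnorm(1, 0, s_cut[k])
        acc <- FALSE
        if (prop > lo_k && prop < hi_k) {
          lr <- ll_cut(k, prop, cuts, eta) - ll_cut(k, cuts[k], cuts, eta)
          acc <- log(stats::runif(1)) < lr
          if (acc) cuts[k] <- prop
        }
        if (it <= warmup)
          s_cut[k] <- exp(log(s_cut[k]) + (as.numeric(acc) - 0.44) / sqrt(it))
      }
      ## latent responses: truncated normal via inverse CDF
      lo <- c(-Inf, cuts)[y]; hi <- c(cuts, Inf)[y]
      plo <- stats::pnorm(lo - eta); phi_ <- stats::pnorm(hi - eta)
      uu <- plo + stats::runif(n) * pmax(phi_ - plo, 1e-12)
      z <- eta + stats::qnorm(pmin(pmax(uu, 1e-12), 1 - 1e-12))
      ## beta: conjugate normal update
      rhs <- crossprod(X, z - u[subj])
      mu_b <- backsolve(cA, forwardsolve(t(cA), rhs))
      beta <- drop(mu_b + backsolve(cA, stats::rnorm(p)))
      ## subject intercepts: conjugate normal update
      r <- z - drop(X %*% beta)
      ssum <- drop(rowsum(r, subj))
      prec <- ns + 1 / sigma_u^2
      u <- stats::rnorm(S, ssum / prec, sqrt(1 / prec))
      ## sigma_u: RW Metropolis on the log scale, half-t prior
      ls <- log(sigma_u)
      ls_p <- ls + stats::rnorm(1, 0, s_ls)
      lpost <- function(l) sum(stats::dnorm(u, 0, exp(l), log = TRUE)) +
        .halft_logprior(exp(l), prior$sigma_df, prior$sigma_scale) + l
      acc2 <- log(stats::runif(1)) < lpost(ls_p) - lpost(ls)
      if (acc2) sigma_u <- exp(ls_p)
      if (it <= warmup)
        s_ls <- exp(log(s_ls) + (as.numeric(acc2) - 0.44) / sqrt(it))
      ## joint location shift (u - delta, cuts - delta): leaves the
      ## likelihood invariant, so it is accepted on the prior ratio alone;
      ## decorrelates the cutpoints from the intercept mean
      delta <- stats::rnorm(1, 0, s_sh)
      lr3 <- sum(stats::dnorm(u - delta, 0, sigma_u, log = TRUE) -
                   stats::dnorm(u, 0, sigma_u, log = TRUE)) +
        sum(stats::dt((cuts - delta) / prior$cut_scale, prior$cut_df,
                      log = TRUE) -
              stats::dt(cuts / prior$cut_scale, prior$cut_df, log = TRUE))
      acc3 <- log(stats::runif(1)) < lr3
      if (acc3) { u <- u - delta; cuts <- cuts - delta }
      if (it <= warmup)
        s_sh <- exp(log(s_sh) + (as.numeric(acc3) - 0.44) / sqrt(it))
      if (it > warmup)
        out[it - warmup, ] <- c(beta, cuts, sigma_u, u)
    }
    out
  }

  chain_draws <- lapply(seq_len(chains), function(ch)
    run_chain(split_seed(seed, 97L, ch)))
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- parnames
  chain_id <- rep(seq_len(chains), each = iter)

  diag_par <- seq_len(p + (K - 1) + 1)   # betas, cutpoints, sigma_u
  rhat <- vapply(diag_par, function(j)
    split_rhat(matrix(draws[, j], nrow = iter)), numeric(1))
  ess <- vapply(diag_par, function(j)
    ess_basic(matrix(draws[, j], nrow = iter)), numeric(1))
  names(rhat) <- names(ess) <- parnames[diag_par]

  out <- list(draws = draws, chain = chain_id,
              diagnostics = list(rhat = rhat, ess = ess,
                                 unreliable = any(rhat >= 1.01, na.rm = TRUE)),
              parnames = parnames, p = p, K = K, S = S,
              X = X, y = y, subject = subj,
              prior = prior, chains = chains, warmup = warmup, iter = iter,
              seed = seed, terms = attr(mf, "terms"),
              call = match.call())
  class(out) <- "oprobit_fit"
  out
}

# split-Rhat from a draws matrix (rows = iterations, cols = chains)
split_rhat <- function(m) {
  half <- floor(nrow(m) / 2)
  sm <- cbind(m[seq_len(half), , drop = FALSE],
              m[(nrow(m) - half + 1):nrow(m), , drop = FALSE])
  nn <- nrow(sm); mm <- ncol(sm)
  mu <- colMeans(sm)
  B <- nn * stats::var(mu)
  W <- mean(apply(sm, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# basic effective sample size (Geyer initial positive sequence, pooled)
ess_basic <- function(m) {
  nn <- nrow(m); mm <- ncol(m)
  ac <- rowMeans(vapply(seq_len(mm), function(j) {
    x <- m[, j] - mean(m[, j])
    v <- sum(x^2) / nn
    if (v == 0) return(rep(0, min(nn - 1, 200)))
    vapply(seq_len(min(nn - 1, 200)), function(l)
      sum(x[1:(nn - l)] * x[(l + 1):nn]) / nn / v, numeric(1))
  }, numeric(min(nn - 1, 200))))
  # sum over pairs while the pair sums stay positive
  rho_sum <- 0
  l <- 1
  while (l + 1 <= length(ac)) {
    pr <- ac[l] + ac[l + 1]
    if (pr <= 0) break
    rho_sum <- rho_sum + pr
    l <- l + 2
  }
  nn * mm / (1 + 2 * rho_sum)
}

#' Highest-density interval of posterior draws
#'
#' Shortest interval containing `mass` of the draws (sorted-window
#' algorithm; ties broken toward the lower start).
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param mass probability mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) stop("need at least 100 draws")
  s <- sort(draws)
  n <- length(s)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[(k + 1):n] - s[1:(n - k)]
  i <- which.min(widths)
  c(s[i], s[i + k])
}

#' Evidence ratio for a directed effect
#'
#' `ER+ = P(theta > 0) / P(theta <= 0)` estimated from draw proportions
#' (`ER-` is the reciprocal convention for negative effects). When no draw
#' opposes the direction the ratio is infinite, reported as `Inf`.
#'
#' @param draws posterior draws of the effect.
#' @param direction `"positive"` (ER+) or `"negative"` (ER-).
#' @return the evidence ratio (possibly `Inf`).
#' @examples
#' evidence_ratio(c(rep(1, 95), rep(-1, 5)))  # 19
#' @export
evidence_ratio <- function(draws, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (!length(draws)) stop("draws must be nonempty")
  n_pos <- sum(draws > 0)
  n_for <- if (direction == "positive") n_pos else length(draws) - n_pos
  n_against <- length(draws) - n_for
  if (n_against == 0) return(Inf)
  n_for / n_against
}

#' Unadjusted Bayesian R-squared on the latent scale
#'
#' Per draw: `var(eta) / (var(eta) + 1)` with `eta = X beta + u[subject]`
#' and residual variance fixed at 1 (the probit scale); the
#' subject-intercept contribution counts as explained variance.
#'
#' @param fit an `oprobit_fit`.
#' @return list with `draws` (one R2 per posterior draw), `mean`, `hdi`.
#' @export
bayes_r2 <- function(fit) {
  p <- fit$p; K <- fit$K; S <- fit$S
  bidx <- seq_len(p)
  uidx <- p + (K - 1) + 1 + seq_len(S)
  eta <- fit$draws[, bidx, drop = FALSE] %*% t(fit$X) +
    fit$draws[, uidx, drop = FALSE][, fit$subject, drop = FALSE]
  v <- apply(eta, 1, stats::var)
  r2 <- v / (v + 1)
  list(draws = r2, mean = mean(r2), hdi = hdi(r2))
}

#' @export
coef.oprobit_fit <- function(object, ...) {
  colMeans(object$draws[, seq_len(object$p), drop = FALSE])
}

#' Posterior summary of an ordered probit fit
#'
#' @param object an `oprobit_fit`.
#' @param er_direction optional named character vector
#'   (`"positive"`/`"negative"`) selecting the reported evidence-ratio
#'   direction per coefficient; default `"positive"` for all.
#' @param mass HDI mass (default 0.95).
#' @param ... unused.
#' @return data.frame: `parameter`, `mean`, `sd`, `hdi_lo`, `hdi_hi`,
#'   `er_direction`, `er`, `rhat`, `ess`.
#' @export
summary.oprobit_fit <- function(object, er_direction = NULL, mass = 0.95,
                                ...) {
  idx <- seq_len(object$p + (object$K - 1) + 1)
  nm <- object$parnames[idx]
  tab <- data.frame(parameter = nm,
                    mean = colMeans(object$draws[, idx, drop = FALSE]),
                    sd = apply(object$draws[, idx, drop = FALSE], 2,
                               stats::sd),
                    stringsAsFactors = FALSE)
  h <- t(apply(object$draws[, idx, drop = FALSE], 2, hdi, mass = mass))
  tab$hdi_lo <- h[, 1]; tab$hdi_hi <- h[, 2]
  dirs <- rep("positive", length(idx))
  names(dirs) <- nm
  if (!is.null(er_direction)) dirs[names(er_direction)] <- er_direction
  tab$er_direction <- dirs
  tab$er <- vapply(seq_along(idx), function(j)
    evidence_ratio(object$draws[, idx[j]], dirs[j]), numeric(1))
  tab$rhat <- object$diagnostics$rhat[nm]
  tab$ess <- object$diagnostics$ess[nm]
  rownames(tab) <- NULL
  tab
}

#' @export
print.oprobit_fit <- function(x, ...) {
  cat(sprintf("Hierarchical ordered probit: %d obs, %d subjects, K = %d\n",
              length(x$y), x$S, x$K))
  cat(sprintf("  %d chains x %d draws (+%d warmup)%s\n",
              x$chains, x$iter, x$warmup,
              if (x$diagnostics$unreliable)
                "  [WARNING: Rhat >= 1.01, results unreliable]" else ""))
  print(summary(x), digits = 3)
  invisible(x)
}

#' Posterior predictive category probabilities
#'
#' Average over posterior draws of `P(y = k | x)` for new rows; subject
#' intercepts are integrated out (`u ~ N(0, sigma_u)`) unless the row's
#' subject was in the fit, in which case the posterior `u_s` draws are
#' used.
#'
#' @param object an `oprobit_fit`.
#' @param newdata data.frame with the model covariates (and optionally the
#'   subject column used in the fit).
#' @param thin keep every `thin`-th draw (default 10).
#' @param ... unused.
#' @return matrix, rows = newdata rows, columns = categories `1..K`.
#' @export
predict.oprobit_fit <- function(object, newdata, thin = 10L, ...) {
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  keep <- seq(1, nrow(object$draws), by = thin)
  K <- object$K; p <- object$p
  cut_idx <- p + seq_len(K - 1)
  sig_idx <- p + K
  probs <- matrix(0, nrow(X), K)
  for (d in keep) {
    beta <- object$draws[d, seq_len(p)]
    cuts <- object$draws[d, cut_idx]
    sig <- object$draws[d, sig_idx]
    eta <- drop(X %*% beta)
    sd_tot <- sqrt(1 + sig^2)
    cum <- vapply(cuts, function(cc) stats::pnorm((cc - eta) / sd_tot),
                  numeric(length(eta)))
    cum <- cbind(matrix(cum, ncol = K - 1), 1)
    probs <- probs + cbind(cum[, 1, drop = FALSE],
                           cum[, -1, drop = FALSE] -
                             cum[, -K, drop = FALSE])
  }
  probs / length(keep)
}

#' Simulate responses from the posterior of an ordered probit fit
#'
#' @param object an `oprobit_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return integer matrix, `length(y)` rows x `nsim` columns.
#' @export
simulate.oprobit_fit <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(seed)
  n <- length(object$y); p <- object$p; K <- object$K
  picks <- sample(nrow(object$draws), nsim, replace = TRUE)
  out <- matrix(NA_integer_, n, nsim)
  for (j in seq_len(nsim)) {
    d <- picks[j]
    beta <- object$draws[d, seq_len(p)]
    cuts <- object$draws[d, p + seq_len(K - 1)]
    uidx <- p + K + seq_len(object$S)
    eta <- drop(object$X %*% beta) + object$draws[d, uidx][object$subject]
    out[, j] <- findInterval(eta + stats::rnorm(n), cuts) + 1L
  }
  out
}

#' Fit the behavioral probit model (time, BV, AE, BV x AE)
#'
#' Model 1 of the analysis: thought-probe responses from the random-task
#' blocks regressed on time (probe number, z-scored), grand-z BV, grand-z
#' AE and their interaction, with subject random intercepts. Evidence
#' ratios follow the study's directional conventions: ER+ for time, BV and
#' BV x AE; ER- for AE.
#'
#' @param features a [probe_features()] table.
#' @param ... passed to [oprobit_hier()] (chains, iter, seed, ...).
#' @return list of class `oprobit_report`: `fit`, `summary` (directional
#'   ERs), `r2`, `n`.
#' @export
run_model1 <- function(features, ...) {
  d <- features[features$condition == "random" & !features$excluded, ]
  d <- d[stats::complete.cases(d[c("response", "bv", "ae")]), ]
  d$time <- as.numeric(scale(d$probe_index))
  fit <- oprobit_hier(response ~ time + bv + ae + bv:ae, d, ...)
  dirs <- c(time = "positive", bv = "positive", ae = "negative",
            `bv:ae` = "positive")
  .oprobit_report(fit, dirs, nrow(d))
}

#' Fit the pupillometric probit model (time, tonic, phasic, tonic x phasic)
#'
#' Model 2 of the analysis: responses from the random-task blocks of
#' subjects with usable pupil data, regressed on time and the
#' within-subject z-scored tonic and phasic features averaged over the 25
#' trials preceding each probe. Rows excluded by the 40% missing-pupil rule
#' are dropped. ER directions: ER+ for time, tonic and tonic x phasic;
#' ER- for phasic.
#'
#' @param features a [probe_features()] table with `tonic`/`phasic` filled
#'   (see [add_pupil_features()]).
#' @param ... passed to [oprobit_hier()].
#' @return list of class `oprobit_report`.
#' @export
run_model2 <- function(features, ...) {
  d <- features[features$condition == "random" & !features$excluded, ]
  d <- d[stats::complete.cases(d[c("response", "tonic", "phasic")]), ]
  d$time <- as.numeric(scale(d$probe_index))
  fit <- oprobit_hier(response ~ time + tonic + phasic + tonic:phasic, d, ...)
  dirs <- c(time = "positive", tonic = "positive", phasic = "negative",
            `tonic:phasic` = "positive")
  .oprobit_report(fit, dirs, nrow(d))
}

#' Fit the BV-by-task-condition probit model
#'
#' Supplementary model testing whether task condition modulates the
#' BV/mind-wandering relationship; runs on both conditions with a
#' BV x task interaction.
#'
#' @param features a [probe_features()] table.
#' @param ... passed to [oprobit_hier()].
#' @return list of class `oprobit_report`.
#' @export
run_model_bv_task <- function(features, ...) {
  d <- features[!features$excluded &
                  stats::complete.cases(features[c("response", "bv")]), ]
  d$time <- as.numeric(scale(d$probe_index))
  d$task <- as.numeric(d$condition == "random") - 0.5
  fit <- oprobit_hier(response ~ time + bv + task + bv:task, d, ...)
  dirs <- c(time = "positive", bv = "positive", task = "positive",
            `bv:task` = "negative")
  .oprobit_report(fit, dirs, nrow(d))
}

.oprobit_report <- function(fit, dirs, n) {
  out <- list(fit = fit,
              summary = summary(fit, er_direction = dirs),
              r2 = bayes_r2(fit),
              n = n)
  class(out) <- "oprobit_report"
  out
}

#' @export
print.oprobit_report <- function(x, ...) {
  cat(sprintf("Ordered probit report (%d probe responses)\n", x$n))
  cat(sprintf("  unadjusted Bayesian R2 = %.2f [%.2f, %.2f]\n",
              x$r2$mean, x$r2$hdi[1], x$r2$hdi[2]))
  print(x$summary[seq_len(x$fit$p), ], digits = 3, row.names = FALSE)
  invisible(x)
}
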