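test_that("ordered probit log-likelihood collapses to binary probit at K = 2", {
  set.seed(1)
  X <- cbind(x = stats::rnorm(40))
  beta <- 0.7
  y <- ifelse(stats::rnorm(40, X %*% beta) > 0, 2L, 1L)
  subj <- rep(1L, 40)
  ll <- ordered_probit_loglik(y, X, subj, beta, cutpoints = 0,
                              u = 0, sigma_u = 1, K = 2,
                              include_ranef_density = FALSE)
  eta <- drop(X %*% beta)
  ll_binary <- sum(log(ifelse(y == 2, stats::pnorm(eta),
                              stats::pnorm(-eta))))
  expect_equal(ll, ll_binary, tolerance = 1e-10)
  # non-monotone cutpoints are a rejected state
  expect_identical(ordered_probit_loglik(y, X, subj, beta, c(1, 0.5, 2),
                                         u = 0, K = 4), -Inf)
})

test_that("category probabilities telescope to one for any linear predictor", {
  cuts <- c(-1.2, -0.3, 0.4, 1.1, 2.0)
  for (eta in c(-3, -0.5, 0, 0.8, 4)) {
    p <- diff(c(0, stats::pnorm(cuts - eta), 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("marginal likelihood by quadrature matches Monte Carlo integration", {
  # tiny design: 3 subjects x 4 rows, integrate the random intercept out
  set.seed(9)
  X <- cbind(x = stats::rnorm(12))
  subj <- rep(1:3, each = 4)
  beta <- 0.5; cuts <- c(-1, 0, 1); sigma_u <- 0.8
  y <- simulate_probe_response(X, beta, cuts,
                               u = stats::rnorm(3, 0, sigma_u)[subj],
                               seed = 2)
  row_lik <- function(rows, u) {
    lo <- c(-Inf, cuts)[y[rows]]
    hi <- c(cuts, Inf)[y[rows]]
    vapply(u, function(uu) {
      eta_u <- drop(X[rows, , drop = FALSE] %*% beta) + uu
      prod(stats::pnorm(hi - eta_u) - stats::pnorm(lo - eta_u))
    }, numeric(1))
  }
  marg_quad <- vapply(1:3, function(s) {
    rows <- which(subj == s)
    stats::integrate(function(u) row_lik(rows, u) *
                       stats::dnorm(u, 0, sigma_u),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  set.seed(33)
  udraws <- stats::rnorm(2e5, 0, sigma_u)
  marg_mc <- vapply(1:3, function(s)
    mean(row_lik(which(subj == s), udraws)), numeric(1))
  expect_equal(marg_quad, marg_mc, tolerance = 0.01)
})

test_that("HDI matches the analytic normal interval and degenerate cases", {
  set.seed(17)
  d <- stats::rnorm(1e6)
  h <- hdi(d)
  expect_equal(h[1], -1.96, tolerance = 0.02)
  expect_equal(h[2], 1.96, tolerance = 0.02)
  # symmetric unimodal draws: HDI close to the equal-tail interval
  et <- stats::quantile(d, c(0.025, 0.975))
  expect_equal(unname(h), unname(et), tolerance = 0.02)
  # point mass -> zero width
  expect_equal(diff(hdi(rep(3.3, 200))), 0)
  expect_error(hdi(stats::rnorm(50)), "100 draws")
})

test_that("evidence ratios follow the draw-proportion arithmetic", {
  expect_equal(evidence_ratio(c(rep(1, 95), rep(-1, 5))), 19)
  expect_equal(evidence_ratio(c(rep(1, 50), rep(-1, 50))), 1)
  expect_identical(evidence_ratio(rep(1, 100)), Inf)
  expect_equal(evidence_ratio(c(rep(1, 5), rep(-1, 95)), "negative"), 19)
  # ER+ and ER- are reciprocal when both are finite
  d <- c(rep(1, 80), rep(-1, 20))
  expect_equal(evidence_ratio(d) * evidence_ratio(d, "negative"), 1)
  expect_error(evidence_ratio(numeric(0)), "nonempty")
})

test_that("ER from draws agrees with the analytic posterior in a conjugate case", {
  # Normal likelihood, normal prior -> normal posterior with known tail mass
  set.seed(5)
  obs <- 0.4; sd_obs <- 0.5; sd_prior <- 2
  post_var <- 1 / (1 / sd_obs^2 + 1 / sd_prior^2)
  post_mean <- post_var * obs / sd_obs^2
  draws <- stats::rnorm(2e5, post_mean, sqrt(post_var))
  p_pos <- stats::pnorm(0, post_mean, sqrt(post_var), lower.tail = FALSE)
  expect_equal(evidence_ratio(draws), p_pos / (1 - p_pos), tolerance = 0.05)
})

test_that("the sampler is deterministic given a seed and flags its diagnostics", {
  d <- make_probit_sim(n_sub = 8, n_probe = 10, seed = 3)
  f1 <- oprobit_hier(response ~ time + bv, d, chains = 2, warmup = 80,
                     iter = 120, seed = 42)
  f2 <- oprobit_hier(response ~ time + bv, d, chains = 2, warmup = 80,
                     iter = 120, seed = 42)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1), summary(f2))
  expect_named(f1$diagnostics, c("rhat", "ess", "unreliable"))
  f3 <- oprobit_hier(response ~ time + bv, d, chains = 2, warmup = 80,
                     iter = 120, seed = 43)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the sampler recovers generating coefficients at study scale", {
  d <- make_probit_sim(seed = 12)
  fit <- oprobit_hier(response ~ time + bv + ae + bv:ae, d,
                      chains = 2, warmup = 300, iter = 700, seed = 5)
  s <- summary(fit)
  truth <- c(time = 0.09, bv = 0.33, ae = -0.09, `bv:ae` = 0.07)
  for (nm in names(truth)) {
    row <- s[s$parameter == nm, ]
    expect_lt(abs(row$mean - truth[[nm]]), 2 * row$sd)
  }
  expect_true(all(s$rhat < 1.05, na.rm = TRUE))
})

test_that("Bayesian R2 is bounded, near zero under the null, grows with effects", {
  # null: no effects, no subject variance in the generator
  set.seed(21)
  n <- 300
  d0 <- data.frame(response = simulate_probe_response(
    matrix(0, n, 1), 0, seq(-2, 2, 1), seed = 8),
    x = stats::rnorm(n), subject = rep(1:10, each = 30))
  f0 <- oprobit_hier(response ~ x, d0, chains = 2, warmup = 150,
                     iter = 300, seed = 2)
  r0 <- bayes_r2(f0)
  expect_true(all(r0$draws >= 0 & r0$draws <= 1))
  expect_lt(r0$mean, 0.1)
  # strong effect: R2 clearly larger
  xs <- stats::rnorm(n)
  ds <- data.frame(response = simulate_probe_response(
    cbind(xs), 1.5, seq(-2, 2, 1), seed = 9),
    x = xs, subject = rep(1:10, each = 30))
  fs <- oprobit_hier(response ~ x, ds, chains = 2, warmup = 150,
                     iter = 300, seed = 2)
  expect_gt(bayes_r2(fs)$mean, r0$mean + 0.2)
})

test_that("model-1 wrapper uses exactly the random-condition probe rows", {
  cfg <- sim_config(n_subjects = 6, seed = 19)
  ses <- simulate_session(cfg)
  pf <- probe_features(ses)
  rep1 <- run_model1(pf, chains = 2, warmup = 100, iter = 200, seed = 1)
  expect_equal(rep1$n, sum(pf$condition == "random" & !pf$excluded))
  expect_setequal(rep1$summary$parameter[1:4],
                  c("time", "bv", "ae", "bv:ae"))
  expect_equal(rep1$summary$er_direction[rep1$summary$parameter == "ae"],
               "negative", ignore_attr = TRUE)
  expect_true(rep1$r2$mean >= 0 && rep1$r2$mean <= 1)
})

test_that("model-2 wrapper consumes pupil features and drops excluded probes", {
  set.seed(30)
  n_sub <- 5; n_probe <- 12
  pf <- expand.grid(probe_index = 1:n_probe, subject = 1:n_sub)
  pf$block <- pf$probe_index
  pf$condition <- "random"
  pf$bv_raw <- NA; pf$bv_log <- NA; pf$bv <- NA
  pf$ae_raw <- NA; pf$ae <- NA
  pf$tonic <- stats::rnorm(nrow(pf))
  pf$phasic <- stats::rnorm(nrow(pf))
  pf$excluded <- FALSE
  pf$reason <- NA_character_
  X <- cbind(rep(as.numeric(scale(1:n_probe)), n_sub),
             pf$tonic, pf$phasic, pf$tonic * pf$phasic)
  pf$response <- simulate_probe_response(
    X, c(0.08, -0.12, -0.13, -0.36), seq(-2, 2, 1),
    u = stats::rnorm(n_sub, 0, 0.5)[pf$subject], seed = 3)
  pf$excluded[1:3] <- TRUE   # pupil missing-data exclusions
  rep2 <- run_model2(pf, chains = 2, warmup = 100, iter = 200, seed = 2)
  expect_equal(rep2$n, nrow(pf) - 3)
  expect_setequal(rep2$summary$parameter[1:4],
                  c("time", "tonic", "phasic", "tonic:phasic"))
})

test_that("posterior prediction and simulation methods are coherent", {
  d <- make_probit_sim(n_sub = 6, n_probe = 10, seed = 44)
  fit <- oprobit_hier(response ~ time + bv, d, chains = 2, warmup = 80,
                      iter = 150, seed = 7)
  pr <- predict(fit, newdata = d[1:5, ], thin = 5)
  expect_equal(dim(pr), c(5, 6))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-9)
  expect_true(all(pr >= 0))
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(nrow(d), 3))
  expect_true(all(sims %in% 1:6))
})

test_that("the BV-by-task model runs on both conditions", {
  cfg <- sim_config(n_subjects = 5, seed = 71)
  pf <- probe_features(simulate_session(cfg))
  repbt <- run_model_bv_task(pf, chains = 2, warmup = 80, iter = 150,
                             seed = 4)
  expect_equal(repbt$n, sum(!pf$excluded))
  expect_true("bv:task" %in% repbt$summary$parameter)
  expect_true(all(c("random", "alternating") %in%
                    pf$condition[!pf$excluded]))
})

test_that("the log-density equals per-row category-probability products", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:15, 1); p <- sample(1:3, 1); S <- sample(2:4, 1)
    X <- matrix(stats::rnorm(n * p), n, p)
    beta <- stats::rnorm(p)
    cuts <- sort(stats::rnorm(5))
    subj <- sample(seq_len(S), n, replace = TRUE)
    u <- stats::rnorm(S)
    y <- sample(1:6, n, replace = TRUE)
    ll <- ordered_probit_loglik(y, X, subj, beta, cuts, u, sigma_u = 1,
                                K = 6, include_ranef_density = FALSE)
    ll_direct <- sum(vapply(seq_len(n), function(r) {
      eta <- sum(X[r, ] * beta) + u[subj[r]]
      probs <- diff(c(0, stats::pnorm(cuts - eta), 1))
      log(probs[y[r]])
    }, numeric(1)))
    expect_equal(ll, ll_direct, tolerance = 1e-10)
  }
})
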