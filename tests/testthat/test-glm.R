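test_that("double-gamma HRF has the canonical shape", {
  expect_equal(double_gamma_hrf(0), 0, tolerance = 1e-6)
  grid <- seq(0, 32, by = 0.01)
  h <- double_gamma_hrf(grid)
  expect_equal(max(h), 1, tolerance = 1e-9)
  expect_equal(grid[which.max(h)], 6, tolerance = 0.1)
  # one positive lobe then one undershoot: exactly one sign change
  sgn <- sign(h[h != 0])
  expect_equal(sum(diff(sgn) != 0), 1)
  expect_lt(min(h), 0)
  expect_error(double_gamma_hrf(1, peak = -2), "invalid")
})

test_that("event regressors are linear and superpose exactly", {
  tr <- 1.8; nv <- 120
  expect_equal(events_to_regressor(numeric(0), 0, tr, nv), numeric(nv))
  r1 <- events_to_regressor(20, 0, tr, nv)
  r2 <- events_to_regressor(80, 0, tr, nv)
  r12 <- events_to_regressor(c(20, 80), 0, tr, nv)
  expect_lt(max(abs(r12 - (r1 + r2))), 1e-9)
  # doubling amplitude doubles the column
  r2x <- events_to_regressor(20, 0, tr, nv, amplitudes = 2)
  expect_equal(r2x, 2 * r1, tolerance = 1e-12)
  # unit impulse at t = 0 returns the kernel sampled at volume times
  imp <- events_to_regressor(0, 0, tr, nv)
  expect_lt(max(abs(imp - double_gamma_hrf((0:(nv - 1)) * tr))), 1e-6)
  expect_warning(events_to_regressor(c(10, 1000), 0, tr, nv), "dropped")
})

test_that("pre-probe boxcars split by label and honor the interval", {
  tr <- 1.8; nv <- 100
  probes <- c(60, 120)
  bx <- preprobe_boxcars(probes, off_task = c(TRUE, FALSE), tr, nv)
  expect_equal(colnames(bx), c("off_task", "on_task"))
  # all probes on-task -> off-task column is identically zero
  bx_on <- preprobe_boxcars(probes, off_task = c(FALSE, FALSE), tr, nv)
  expect_true(all(bx_on[, "off_task"] == 0))
  expect_true(any(bx_on[, "on_task"] != 0))
  # the 18 s variant differs only through the boxcar duration
  bx18 <- preprobe_boxcars(probes, c(TRUE, FALSE), tr, nv, interval = 18)
  expect_gt(max(bx18[, "off_task"]), max(bx[, "off_task"]))
  # probe earlier than the interval start: truncated at the block start
  bx_tr <- preprobe_boxcars(5, TRUE, tr, nv, interval = 10)
  bx_full <- preprobe_boxcars(50, TRUE, tr, nv, interval = 10)
  expect_lt(max(bx_tr[, "off_task"]), max(bx_full[, "off_task"]))
})

test_that("marker regressors hold values at the nearest anchor", {
  tr <- 2; nv <- 10
  # constant series -> constant column
  expect_equal(marker_regressor(c(3, 9), c(4, 4), tr, nv),
               rep(4, nv))
  # two anchors: nearest rule switches at the midpoint (tie -> earlier)
  col <- marker_regressor(c(2, 10), c(1, 5), tr, nv)
  vol_t <- (0:(nv - 1)) * tr
  expect_equal(col, ifelse(vol_t <= 6, 1, 5))
  # volumes before the first anchor take the first value
  expect_equal(col[1], 1)
  # convolve mode equals the events_to_regressor composition
  vals <- c(0.5, 2)
  expect_equal(marker_regressor(c(5, 11), vals, tr, nv, mode = "convolve"),
               events_to_regressor(c(5, 11), 0, tr, nv, amplitudes = vals))
  expect_error(marker_regressor(numeric(0), numeric(0), tr, nv), "empty")
})

test_that("DCT basis is orthonormal and soaks up linear drift", {
  nv <- 200; tr <- 1.8
  B <- dct_basis(nv, tr, cutoff_s = 128)
  expect_gt(ncol(B), 0)
  G <- crossprod(B)
  expect_equal(G, diag(ncol(B)), tolerance = 1e-9, ignore_attr = TRUE)
  # lowest column is a monotone half-cosine
  expect_true(all(diff(B[, 1]) < 0))
  # projecting out the basis removes > 99% of a linear drift's variance
  drift <- seq(-1, 1, length.out = nv)
  drift <- drift - mean(drift)
  resid <- drift - B %*% crossprod(B, drift)
  expect_lt(sum(resid^2) / sum(drift^2), 0.01)
})

test_that("GLM estimation is exact without noise and calibrated under the null", {
  set.seed(6)
  nv <- 150
  X <- cbind(intercept = 1,
             task = events_to_regressor(seq(10, 250, by = 25), 0, 1.8, nv),
             dct_basis(nv, 1.8))
  dims <- c(8, 8, 6)
  truth <- array(0, c(dims, ncol(X)))
  truth[3:5, 3:5, 2:4, 2] <- 1.2
  Y0 <- simulate_bold(X, truth, noise_sd = 0, seed = 1)
  fit0 <- fit_glm(Y0, X, contrast = c(0, 1, rep(0, ncol(X) - 2)))
  expect_equal(fit0$beta, truth, tolerance = 1e-8)
  # null calibration: ~5% of |z| > 1.96
  Yn <- simulate_bold(X, array(0, c(dims, ncol(X))), noise_sd = 1, seed = 2)
  fitn <- fit_glm(Yn, X, contrast = c(0, 1, rep(0, ncol(X) - 2)))
  expect_lt(abs(mean(abs(fitn$zmap) > 1.96) - 0.05), 0.025)
  # contrast [1, -1] equals the difference of single-column effects
  c1 <- fit_glm(Yn, X, c(1, 0, rep(0, ncol(X) - 2)))
  c2 <- fit_glm(Yn, X, c(0, 1, rep(0, ncol(X) - 2)))
  c12 <- fit_glm(Yn, X, c(1, -1, rep(0, ncol(X) - 2)))
  b1 <- c1$beta[, , , 1]; b2 <- c2$beta[, , , 2]
  expect_equal(drop(b1 - b2),
               drop(c12$beta[, , , 1] - c12$beta[, , , 2]),
               tolerance = 1e-10)
  expect_warning(fit_glm(Yn, cbind(X, X[, 2]), c(0, 1, rep(0, ncol(X) - 1))),
                 "rank deficient")
})

test_that("thresholding labels 26-connected clusters and prunes small ones", {
  z <- array(0, c(10, 10, 10))
  expect_equal(sum(threshold_map(z)$mask), 0)
  # one cuboid -> one cluster of its exact size
  z[2:4, 2:4, 2:4] <- 5
  th <- threshold_map(z, 2.3)
  expect_equal(length(th$sizes), 1)
  expect_equal(th$sizes, 27L)
  # two cuboids touching only at a corner join under 26-connectivity
  z2 <- array(0, c(10, 10, 10))
  z2[1:3, 1:3, 1:3] <- 5
  z2[4:6, 4:6, 4:6] <- 5
  th2 <- threshold_map(z2, 2.3)
  expect_equal(length(th2$sizes), 1)
  # separated by one empty plane -> two clusters
  z3 <- array(0, c(10, 10, 10))
  z3[1:3, 1:3, 1:3] <- 5
  z3[5:7, 5:7, 5:7] <- 5
  th3 <- threshold_map(z3, 2.3)
  expect_equal(length(th3$sizes), 2)
  # minimum cluster size prunes
  th4 <- threshold_map(z3, 2.3, min_cluster = 28)
  expect_equal(length(th4$sizes), 0)
  expect_error(threshold_map(array(NA_real_, c(2, 2, 2))), "finite")
})

test_that("atlas overlap percentages cover the map and fail loudly otherwise", {
  dims <- c(6, 6, 6)
  m <- array(FALSE, dims); m[2:5, 2:5, 2:5] <- TRUE
  A <- array(FALSE, dims); A[1:3, , ] <- TRUE
  B <- array(FALSE, dims); B[4:6, , ] <- TRUE
  ov <- atlas_overlap(m, list(A = A, B = B))
  expect_equal(sum(ov$percent), 100, tolerance = 1e-9)
  expect_equal(ov$percent, c(50, 50))
  # map entirely inside one network
  ov1 <- atlas_overlap(m, list(A = array(TRUE, dims), B = B))
  expect_equal(ov1$percent[1], 100)
  # white-matter voxels are ignored
  wm <- array(FALSE, dims); wm[2:5, 2:5, 2] <- TRUE
  ov_wm <- atlas_overlap(m, list(A = A, B = B), wm_mask = wm)
  expect_equal(sum(ov_wm$n_voxels), sum(m) - sum(m & wm))
  # uncovered voxels violate the full-cover contract
  expect_error(atlas_overlap(m, list(A = A)), "not covered")
  tab <- atlas_overlap(m, list(A = A), allow_unassigned = TRUE)
  expect_true("unassigned" %in% tab$parcel)
})

test_that("Dice coefficient matches hand counts", {
  d <- c(10, 1, 1)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:4] <- TRUE          # |A| = 4
  b[2:7] <- TRUE          # |B| = 6, |A.B| = 3
  expect_equal(dice(a, b), 0.6)
  expect_equal(dice(a, a), 1)
  b2 <- array(FALSE, d); b2[6:8] <- TRUE
  expect_equal(dice(a, b2), 0)
  expect_warning(dd <- dice(array(FALSE, d), array(FALSE, d)), "empty")
  expect_equal(dd, 0)
})
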