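test_that("PRF has the stated shape: zero at origin, peak at t_max, closed-form ratio", {
  expect_equal(prf(0), 0)
  expect_equal(prf(900), 1)
  grid <- seq(0, 4000, by = 1)
  expect_equal(grid[which.max(prf(grid))], 900)
  ratio <- prf(450) / prf(900)
  expect_equal(ratio, 0.5^10 * exp(10 * 0.5), tolerance = 1e-12)
  expect_equal(prf(-100), 0)
  expect_error(prf(100, n = -1), "positive")
})

test_that("blink detection finds constructed dropouts and merges close ones", {
  fs <- 100
  set.seed(1)
  x <- 1000 + stats::rnorm(10 * fs)
  # dropout-and-rebound artifact between 4.0 and 4.3 s
  x[(4 * fs):(4.3 * fs)] <- 300
  bl <- detect_blinks(make_trace(x, fs), k = 5)
  expect_equal(nrow(bl), 1)
  expect_lt(abs(bl$onset - 4.0), 2 / fs + 1e-9)
  expect_lt(abs(bl$offset - 4.3), 3 / fs + 1e-9)
  # constant trace: no blinks
  expect_equal(nrow(detect_blinks(make_trace(rep(5, 500), fs))), 0)
  # two NA dropouts closer than the merge distance collapse into one
  y <- rep(1000, 10 * fs)
  y[400:420] <- NA; y[430:450] <- NA
  bl2 <- detect_blinks(make_trace(y, fs), merge_distance = 0.2)
  expect_equal(nrow(bl2), 1)
  bl3 <- detect_blinks(make_trace(y, fs), merge_distance = 0.01)
  expect_equal(nrow(bl3), 2)
  expect_error(detect_blinks(make_trace(numeric(0), fs)), "empty")
})

test_that("blink interpolation is linear, flagged, and conserves bookkeeping", {
  fs <- 100
  ramp <- seq(0, 10, length.out = 5 * fs)
  x <- ramp; x[200:230] <- NA
  tr <- interpolate_blinks(make_trace(x, fs),
                           data.frame(onset = 1.99, offset = 2.30),
                           margin = 0.05)
  expect_false(anyNA(tr$size))
  # linear ramp is reproduced exactly through the gap
  expect_equal(tr$size, ramp, tolerance = 1e-9)
  # masked samples = widened interval [1.94, 2.35] s
  expect_equal(sum(tr$mask == 1L), 42L)
  # flat signal: interpolation equals the flat level
  xf <- rep(7, 300); xf[100:120] <- NA
  trf <- interpolate_blinks(make_trace(xf, fs),
                            data.frame(onset = 0.99, offset = 1.20))
  expect_true(all(trf$size == 7))
})

test_that("low-pass filter is zero-phase, preserves DC and slow components", {
  fs <- 250
  tt <- (0:(10 * fs - 1)) / fs
  expect_equal(lowpass(make_trace(rep(3.7, length(tt)), fs), 5)$size,
               rep(3.7, length(tt)), tolerance = 1e-6)
  # 20 Hz attenuated > 90%
  hi <- sin(2 * pi * 20 * tt)
  out_hi <- lowpass(make_trace(hi, fs), 5)$size
  mid <- seq(2 * fs, 8 * fs)
  expect_lt(max(abs(out_hi[mid])), 0.1)
  # 0.1 Hz preserved within 1%, zero lag (peak cross-correlation at 0)
  lo <- sin(2 * pi * 0.1 * tt)
  out_lo <- lowpass(make_trace(lo, fs), 5)$size
  expect_equal(max(abs(out_lo[mid])), 1, tolerance = 0.01)
  cc <- stats::ccf(out_lo, lo, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(lowpass(make_trace(lo, fs), 200), "cutoff")
})

test_that("downsampling decimates, preserves values and carries the mask", {
  fs <- 1000
  x <- rep(2.5, 4000)
  tr <- make_trace(x, fs)
  tr$mask[1001:1010] <- 1L
  dn <- downsample(tr, 250)
  expect_equal(length(dn$size), 1000)
  expect_true(all(dn$size == 2.5))
  expect_equal(dn$fs, 250)
  # any-masked rule: the 10 masked hi-res samples cover 3 output samples
  expect_equal(sum(dn$mask == 1L), 3)
  # mask fraction conserved within one output sample's worth
  expect_lt(abs(mean(dn$mask != 0) - 10 / 4000), 1 / 1000)
  # event times remain on the common clock within one target sample
  expect_lt(abs(dn$time[round(2.5 * 250) + 1] - 2.5), 1 / 250)
  expect_error(downsample(tr, 300), "divide")
})

test_that("tonic estimation recovers a slow baseline under PRF bumps", {
  fs <- 50; dur <- 90
  tt <- seq(0, dur, by = 1 / fs)
  set.seed(2)
  events <- seq(2, dur - 4, by = 2)
  amps <- stats::runif(length(events), 10, 25)
  D <- sapply(events, function(o) prf((tt - o) * 1000))
  tonic_true <- 1000 + 30 * sin(2 * pi * tt / 25)
  x <- tonic_true + as.numeric(D %*% amps)
  tn <- estimate_tonic(make_trace(x, fs), events)
  expect_lt(max(abs(tn$tonic - tonic_true)) / 30, 0.05)
  expect_true(all(tn$tonic <= x + 1e-9))
  # zero phasic content: tonic tracks the signal itself
  tn0 <- estimate_tonic(make_trace(tonic_true, fs))
  expect_lt(sqrt(mean((tn0$tonic - tonic_true)^2)), 0.1)
})

test_that("phasic NNLS recovery is exact and always non-negative", {
  fs <- 50
  tt <- seq(0, 40, by = 1 / fs)
  events <- seq(2, 36, by = 2)
  set.seed(5)
  amps <- stats::runif(length(events), 0.5, 2)
  D <- sapply(events, function(o) prf((tt - o) * 1000))
  tonic <- rep(100, length(tt))
  tr <- make_trace(tonic + as.numeric(D %*% amps), fs)
  ph <- estimate_phasic(tr, tonic, events)
  expect_lt(max(abs(ph$coef - amps)), 1e-6)
  # trace equal to tonic: all coefficients zero
  ph0 <- estimate_phasic(make_trace(tonic, fs), tonic, events)
  expect_true(all(ph0$coef == 0))
  # negative-going artifact cannot push coefficients below zero
  dip <- tonic; dip[500:520] <- 60
  phd <- estimate_phasic(make_trace(dip, fs), tonic, events)
  expect_true(all(phd$coef >= 0))
  expect_warning(estimate_phasic(tr, tonic, c(5, 5.02)), "50 ms")
  expect_error(estimate_phasic(tr, tonic, 1000), "span")
})

test_that("trial features sum coefficients in the 200 ms window", {
  fs <- 50
  tt <- seq(0, 20, by = 1 / fs)
  dec <- list(tonic = 100 + tt,
              events = data.frame(onset = c(5, 5.1, 5.3, 10),
                                  coef = c(1, 2, 4, 8)),
              trace = make_trace(100 + tt, fs))
  fx <- trial_features(dec, stim_onsets = c(5, 10), soa = 0.75)
  # stimulus at 5 s: events at 5 and 5.1 are inside +/-200 ms, 5.3 is not
  expect_equal(fx$phasic, c(3, 8))
  expect_equal(fx$tonic, c(105, 110))
  expect_equal(fx$missing_fraction, c(0, 0))
  expect_error(trial_features(dec, 100), "outside")
})

test_that("probe pupil features apply the 40% missing rule", {
  trials <- data.frame(onset = (1:50) * 0.75,
                       tonic = rep(c(1, 3), 25),
                       phasic = rep(2, 50),
                       missing_fraction = 0)
  out <- probe_pupil_features(trials, probe_trial_index = c(25, 50))
  expect_equal(out$n_valid, c(25, 25))
  expect_equal(out$phasic, c(2, 2))
  # one trial 50% missing is dropped from the average
  trials2 <- trials
  trials2$missing_fraction[50] <- 0.5
  trials2$tonic[50] <- 1000
  out2 <- probe_pupil_features(trials2, probe_trial_index = 50)
  expect_equal(out2$n_valid, 24)
  expect_lt(out2$tonic, 10)
  # fully missing window -> excluded
  trials3 <- trials
  trials3$missing_fraction[26:50] <- 0.9
  out3 <- probe_pupil_features(trials3, probe_trial_index = 50)
  expect_true(out3$excluded)
  # 25 trials at 750 ms SOA span 18.75 s
  expect_equal(diff(range(trials$onset[26:50])) + 0.75, 18.75)
})

test_that("full pipeline round-trip: simulated traces decompose faithfully", {
  cfg <- sim_config(n_subjects = 1, pupil_fs = 50)
  st <- simulate_latent_state(60, params = list(sigma = 0, x0 = 0), seed = 3)
  # events one SOA apart within a short tapping stretch
  ev <- data.frame(onset = seq(4, 40, by = 0.75), type = "stimulus")
  sp <- subject_params(blink_rate = 0,
                       pupil_params = list(tonic_amp = 10, state_gain = 0,
                                           noise_sd = 0, phasic_amp = 25,
                                           decoupling = 0))
  tr <- simulate_pupil(st, ev, sp, cfg, seed = 4, duration = 46)
  dec <- pupil_decompose(tr, ev$onset)
  expect_gt(stats::cor(dec$tonic, tr$truth$tonic), 0.95)
  rmse <- sqrt(mean((dec$events$coef - tr$truth$amplitudes)^2))
  expect_lt(rmse, 0.05 * mean(tr$truth$amplitudes))
  expect_true(all(dec$events$coef >= 0))
  expect_true(all(dec$tonic <= tr$size + 1e-9))
})
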