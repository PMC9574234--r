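---
title: "Modeling mind-wandering markers in the finger-tapping random-sequence generation task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mind-wandering markers in the finger-tapping random-sequence generation task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wandertap)
```

## The task and the measurement problem

In the finger-tapping random-sequence generation task (FT-RSGT),
participants tap left/right buttons in time with a 750 ms metronome.
In *random* blocks they try to produce a maximally unpredictable
left/right sequence; in *alternating* blocks they simply alternate
L-R-L-R. Each block ends after roughly 80 stimuli (74-87) with a
six-point thought probe ("clearly on-task" ... "clearly off-task"), so
probes arrive between 55.5 and 65.25 s after tapping onset (60 s on
average). A session comprises 18 random and 9 alternating blocks in a
pseudorandom order with no two alternating blocks in a row.

The task yields two continuous behavioral markers of attentional state:

* **Behavioral variability (BV)** - the sample SD of the inter-tap
  intervals in a 25-tap window. Rising BV signals loosening
  synchronization with the metronome.
* **Approximate entropy (AE)** - the randomness of the binary L/R
  sequence in the same window, computed with template length $m = 2$
  and exact symbol matching. Falling AE signals drift toward
  stereotyped responding.

Alongside these, pupillometry provides *tonic* (slow baseline) and
*phasic* (event-evoked) components of pupil size, and fMRI provides
whole-brain correlates of all of the above.

`wandertap` implements the full analysis chain plus a synthetic-data
generator rich enough to exercise every stage without any external
data.

## The synthetic generator and what it emulates

Everything downstream is driven by a latent attentional state $s(t)
\in (0,1)$ per subject: a discretized Ornstein-Uhlenbeck process
(time constant $\tau = 30$ s, step 0.25 s) passed through a logistic
map. The OU kernel was chosen because mind-wandering episodes span
multiple seconds, the process is bounded after the logistic transform,
and its lag-$\Delta$ autocorrelation $e^{-\Delta/\tau}$ is a
closed-form target the test suite verifies. The generator couples the
state to the observables:

* tap-time jitter SD is `iti_sd_base + iti_sd_gain * s` (defaults
  20 ms + 80 ms/unit), so windowed BV increases with the state;
* the hand-alternation probability is `1 - rep_bias(s)` with
  `rep_bias(s) = clamp(0.5 - 0.9 s, 0.02, 0.5)`: at $s = 0$ the
  sequence is a fair coin (maximal AE), and with rising state it
  drifts toward predictable alternation, so windowed AE decreases;
* probe responses are drawn from an ordered probit whose latent mean
  combines a time-on-task trend (0.35 per z-scored probe number), the
  z-scored latent state (0.90), and subject intercepts
  ($\sigma_u = 0.5$). Cutpoints (-1.25, -0.30, 0.53, 1.25, 2.08) were
  chosen once so the marginal response distribution resembles the
  empirical one (mean near 2.9 of 6; roughly a third of responses in
  the off-task half);
* pupil traces are baseline + smooth OU drift + one unit-peak
  pupil-response-function (PRF) transient per stimulus and tap, with
  amplitudes shrunk by `1 - 0.6 s` (perceptual decoupling), white
  measurement noise, and Poisson blink dropouts;
* BOLD volumes are `X beta + noise` for a supplied design and
  coefficient map.

Per-block stimulus counts come from a discrete triangular weight on
74-87 exponentially tilted so the mean is exactly 80. One master seed
feeds every stage through a documented splitting hash
(`split_seed`), so sessions are bit-reproducible.

What the generator deliberately does *not* emulate: hemodynamic
nonlinearity, head motion, gaze-position artifacts, EyeLink raw
formats, and any dependence structure between subjects. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative assumptions, not robustness to every pathology of real
recordings.

```{r session}
cfg <- sim_config(n_subjects = 3, seed = 11)
ses <- simulate_session(cfg)
ses
```

## Behavioral markers

`probe_features()` computes, for every probe, BV and AE over the 25
taps preceding the probe onset, applies the log transform to BV
(raw SDs floored at 1 ms so noiseless synthetic data cannot produce
$\log 0$) and the variance-stabilizing transform
$-\ln(\ln 2 - \mathrm{AE})$ to AE (guarded at
$\ln 2 - 10^{-6}$), then grand-z-scores both across subjects.

AE uses the conditional-probability form of approximate entropy: both
$\Phi$ sums run over the common index set of templates that have a
continuation, which makes AE exactly the mean conditional
log-probability of the next symbol. This form is identically zero for
completely predictable sequences (constant or strictly alternating)
and bounded by $\ln 2$ for binary alphabets - the properties the
analysis relies on. The test suite checks it against an exhaustive
window-counting oracle on all binary sequences up to length 12.

```{r behavior}
approximate_entropy(rep(c("L", "R"), length.out = 25))
pf <- probe_features(ses)
head(pf[c("subject", "probe_index", "condition", "response", "bv", "ae")])
```

"The 25 taps preceding" is read as the SD of the 24 intervals among
those 25 taps; the sliding single-trial series counts a trial's own
response as preceding (taps before `onset + SOA`), so a block of $n$
stimuli yields $n - 24$ marker values starting at the 25th trial.
Probe responses are dichotomized either at the fixed 3/4 boundary or
by the subject-specific split point that brings the off-task
proportion closest to 50% (ties toward the smaller cutpoint, i.e.
more off-task).

## Pupil preprocessing and deconvolution

The pupil chain is: velocity-based blink detection (thresholds at
$k = 5$ robust SDs of the smoothed derivative; margins 100 ms; blinks
closer than 200 ms merged), linear interpolation across widened blink
gaps, a zero-phase order-2 Butterworth low-pass (5 Hz default, with
odd-reflection padding so the forward-backward pass has no edge
transient), and integer-factor decimation with an any-masked rule for
the sample mask. All thresholds are exposed; the defaults are the
package's own choices since the source procedure was tuned by visual
inspection.

The tonic/phasic split models the preprocessed trace as a smooth
baseline plus non-negative PRF transients,
$h(t) = (t/t_{\max})^{n} e^{n(1 - t/t_{\max})}$ with $n = 10$,
$t_{\max} = 900$ ms, rescaled to unit peak so fitted coefficients are
amplitudes in signal units. Estimation proceeds in two passes:
troughs with prominence above a threshold anchor a natural spline
(pass 1, with a polynomial fallback below 4 troughs), then the
baseline is refined as a cubic B-spline (knots every 2 s) solved
*jointly* with the non-negative least-squares PRF fit by profiling
the spline out of the NNLS problem (pass 2). The literal
subtract-and-refit recipe proved numerically fragile on constructed
fixtures - overlapping PRF tails bias the troughs and the alternation
converges extremely slowly - whereas the joint solve recovers a slow
sinusoidal baseline to within 0.1% of its amplitude and phasic
amplitudes to machine precision on noiseless traces. The final curve
is clipped to remain at or below the signal, preserving the
lower-envelope interpretation.

Because stimulus and tap regressors sit 0-750 ms apart, individual
coefficients are collinear; per-trial phasic values are therefore the
*sum* of coefficients within 200 ms of each stimulus onset, and tonic
values are the curve sampled at the onset. Trial features are
z-scored within subject; per-probe features average the 25 preceding
trials (18.75 s), ignoring trials with more than 40% missing samples
(missing fraction evaluated over `[onset, onset + 750 ms)`, a span the
source leaves unstated).

```{r pupil}
st <- simulate_latent_state(40, seed = 2)
ev <- data.frame(onset = seq(3, 33, by = 2), type = "stimulus")
sp <- subject_params(blink_rate = 0,
                     pupil_params = list(noise_sd = 0, decoupling = 0))
tr <- simulate_pupil(st, ev, sp, sim_config(pupil_fs = 50), seed = 4,
                     duration = 38)
dec <- pupil_decompose(tr, ev$onset)
dec
max(abs(dec$events$coef - tr$truth$amplitudes))
```

## The hierarchical ordered probit

Probe responses are ordinal; treating them as Gaussian invites
spurious interactions and miscalibrated uncertainty. Responses
$y \in \{1..6\}$ are therefore modeled through a latent normal
variable partitioned by five ordered cutpoints, with subject random
intercepts:

$$P(y_i = k) = \Phi(c_k - \eta_i) - \Phi(c_{k-1} - \eta_i), \qquad
\eta_i = x_i^\top \beta + u_{s(i)}, \quad u_s \sim N(0, \sigma_u^2).$$

Model 1 regresses the random-block responses on time (probe number),
BV, AE and BV x AE; model 2 on time, tonic, phasic and
tonic x phasic, after the pupil exclusions. No intercept enters
$\beta$ - the cutpoints absorb it.

`oprobit_hier()` samples the posterior with a blocked MCMC scheme
written for this model: truncated-normal latent-response augmentation
gives conjugate Gaussian updates for $\beta$ and $u$;
each cutpoint gets a coordinate-wise Metropolis update within its
bracketing interval against the marginal categorical likelihood;
$\log \sigma_u$ gets an adaptive random-walk update under a
half-Student-t(3, 0, 2.5) prior; and a likelihood-invariant joint
location shift of $(u, c)$ decorrelates the cutpoints from the
intercept mean, which is otherwise the slowest direction. Priors are
weakly informative - Normal(0, 2.5) on coefficients, ordered
Student-t(3, 0, 2.5) on cutpoints - and configurable; the source does
not print its priors, so exact numerical agreement with its
coefficients is not expected even on equivalent data. Defaults follow
the published sampler settings (4 chains, 1000 warm-up, 4000
post-warm-up draws); split-$\hat R$ and effective sample sizes are
attached and fits with $\hat R \ge 1.01$ are flagged.

Reporting follows the study's conventions: posterior mean, 95%
highest-density interval (shortest sorted window, ties to the lower
start), and the evidence ratio
$\mathrm{ER}_+ = P(\theta > 0)/P(\theta \le 0)$ computed from draw
counts (so 95% positive draws give exactly 19, and a one-sided
posterior reports $\infty$). The unadjusted Bayesian $R^2$ is
computed on the latent scale per draw as
$\mathrm{var}(\eta)/(\mathrm{var}(\eta) + 1)$, counting the
subject-intercept variance as explained - the source's convention is
not printed, so this choice is documented rather than inferred.

```{r probit}
rep1 <- run_model1(pf, chains = 2, warmup = 200, iter = 400, seed = 3)
rep1
```

(The short chains here keep the vignette light; analyses use the
4 x 1000 + 4000 defaults.)

## fMRI design matrices, GLMs and overlap reporting

Design construction covers the study's regressor taxonomy: stick/boxcar
event regressors convolved with a unit-peak double-gamma HRF (response
peak 6 s, undershoot 16 s, ratio 1/6 - canonical values, since the
source does not print its parameters); 10 s (or 18 s) pre-probe
boxcars split by the dichotomized label and truncated at block starts;
sliding BV/AE and tonic series resampled to the TR by nearest-anchor
hold *without* additional convolution (the 25-tap window already lags
and smooths them; a linear mode exists behind a flag because the
source's figure caption and methods disagree); phasic series convolved
like events; orthonormal DCT drift columns with periods above 128 s;
and smooth-random-walk stand-ins for CSF/WM/FD/motion nuisances.

`fit_glm()` is voxelwise OLS with a contrast t-statistic mapped to z
through the normal quantile transform. `threshold_map()` applies the
primary threshold z > 2.3 and labels 26-connected components;
cluster-level Gaussian-random-field p-values are deliberately not
computed - a minimum cluster size substitutes, and the map metadata
records the deviation. `atlas_overlap()` distributes suprathreshold
voxels (outside white matter) over binarized parcellations and must
account for 100% of them or fail loudly; `dice()` compares binary
maps.

```{r glm}
nvol <- 120
X <- cbind(intercept = 1,
           taps = events_to_regressor(seq(2, 200, 0.75), 0, 1.8, nvol),
           dct_basis(nvol, 1.8))
truth <- array(0, c(8, 8, 6, ncol(X))); truth[3:5, 3:5, 2:4, 2] <- 1
Y <- simulate_bold(X, truth, noise_sd = 1, seed = 9)
zm <- fit_glm(Y, X, c(0, 1, rep(0, ncol(X) - 2)))
thr <- threshold_map(zm$zmap, 2.3, min_cluster = 2)
dice(thr$mask, truth[, , , 2] > 0)
```

## Numerical choices and known limitations

* Problem sizes in the examples and tests (tens of volumes, 50 Hz
  pupil traces, short chains) are scaled-down choices of this package;
  the estimators are size-agnostic.
* The NNLS design for a whole session is prohibitively large;
  deconvolution is intended per block (about 160 events over about
  70 s), which also matches the block-bounded structure of the task.
* `sample.int`-based draws make every stochastic stage reproducible
  from one seed; two sessions with equal configs are bit-identical.
* The split-point search enumerates all five cutpoints - there is no
  approximation to go wrong - and ties deliberately favor labeling
  more responses off-task.
* Degenerate inputs are defined rather than accidental: zero-variance
  tap windows hit the 1 ms BV floor; AE at the $\ln 2$ singularity is
  capped before the transform; empty event lists give zero regressor
  columns; two empty maps have Dice 0 with a warning.
* The probit sampler is a single-site Gibbs/Metropolis scheme, not
  HMC; it matches the published chain/draw counts and passes
  interval-calibration checks, but very small category counts (a
  subject using one response category throughout) will slow cutpoint
  mixing - the attached $\hat R$/ESS diagnostics are the guard.
* Real-data idiosyncrasies (blink-artifact shapes, pink noise in
  BOLD, probe-response satisficing) are outside the generator; claims
  validated here are about estimator correctness, not field
  robustness.
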