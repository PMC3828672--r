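---
title: "Detecting self-paced movements from multi-unit M1 recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting self-paced movements from multi-unit M1 recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An invasive brain–computer interface must decide, from extracellular
recordings alone, whether the subject is about to perform a movement.
`mudetect` implements an offline pipeline for exactly this decision in
its simplest form: classifying short epochs of multi-unit activity (MUA)
from rat primary motor cortex as either preceding a self-paced paddle
press ("hit") or belonging to the background between presses ("no-hit").
Multi-unit activity — unsorted threshold crossings from the handful of
neurons near each electrode — is attractive for chronic interfaces
because it needs no spike sorting and is less sensitive to day-to-day
waveform drift, but it is noisy, and in freely moving animals the noise
is strongly non-stationary (motion and chewing artifacts, background
activity that rises between trials). The pipeline therefore compares
three analysis cases:

* **Case A** — adaptive median-based spike detection on the raw signal;
* **Case B** — discrete-wavelet soft-threshold denoising, then adaptive
  detection;
* **Case C** — detection with a fixed threshold registered once per
  session (the common manual practice).

Because no recording from the original experiment is publicly
deposited, the package ships a synthetic-session generator that
reproduces the statistical structure the analysis relies on; every
stage is validated against the generator's ground truth.

## The signal model and its stages

### Denoising

A recording `x` of length $N$ is decomposed to five levels with an
orthogonal DWT (half-point symmetric boundary extension). All detail
coefficients are shrunk with the soft threshold
$\eta(c) = \mathrm{sign}(c)\,\max(|c| - Th, 0)$ where

$$Th = \gamma\,\sigma\sqrt{2\ln N},$$

$\sigma$ is the noise standard deviation estimated from a
quantile–quantile fit, and $\gamma \in [0.4, 2]$ is a correction factor
scaling the universal threshold. Ten mother wavelets are supported
(Haar, Daubechies 2/4/6, Symlets 2/4/6, Coiflets 2/4/5) — families
whose shapes resemble an extracellular action potential, which is what
makes the spike coefficients stand out above the noise floor. The
approximation band is left untouched, which is standard practice and
means a small fraction of low-frequency noise power (about $2^{-5}$ of
the total for white noise) survives denoising.

Design choices that the method statement leaves open, fixed here once:

* **Q–Q noise estimate.** The estimator is the least-squares slope of
  the empirical order statistics against standard-normal quantiles
  restricted to the central 25th–75th percentile band. The central band
  ignores the heavy tails contributed by spikes, so the estimate tracks
  the noise floor even at high firing rates.
* **One global threshold.** $N$ is the full recording length and the
  same `Th` is applied at all five levels, reading the threshold
  formula as stated once for the whole data vector.
* **Boundary handling.** Symmetric extension minimises edge artifacts
  and keeps the transform perfectly invertible (`Th = 0` reproduces the
  input to floating-point precision; this is asserted for all ten
  wavelets in the tests).

### Spike detection

Spikes are detected per consecutive, non-overlapping 400 ms window with
the adaptive threshold

$$Thr_D = 4\,\sigma_D, \qquad \sigma_D = \frac{\mathrm{median}(|x|)}{0.6745},$$

the median-based noise scale that stays anchored to the noise floor
even when the window contains many or large action potentials (an RMS
estimate would inflate with the firing rate). A spike is a
threshold-crossing excursion; its timestamp is the extremum within 1 ms
of the first crossing, and a 1 ms refractory period suppresses
double-counting (the earlier event wins). Detection uses the absolute
value of the signal by default: multi-unit recordings superpose units
of both polarities, and absolute-value crossing subsumes either choice.
In manual mode the per-channel threshold from the session metadata is
used unchanged for the whole recording.

### Features and trial selection

A trial is three consecutive paddle hits; after the third hit the
paddle retracts for 9 s. Trials are discarded if flagged as failures
(non-preferred limb, premature hit) or if any two of their hits are
less than 200 ms apart; only the first hit of each accepted trial is
analysed. For each accepted trial the feature vector holds spike counts
of the paw-mapped channels in three contiguous 120 ms intervals:

* **hit epoch** — spanning [−400, −40) ms before the hit (default
  anchoring; forelimb muscle activity leads a reach by roughly 300 ms,
  so cortical activity must lead it further, and the last 40 ms are
  excluded as potentially contaminated by the press itself). The
  alternative flush anchoring [−360, 0) is available as a
  `window_spec("flush")` option rather than a silent guess.
* **no-hit epoch** — the same three bins shifted 500 ms earlier,
  spanning [−900, −540) ms, inside the inter-trial transition.

Bins are half-open, so the three counts partition their 360 ms span.
The dataset is exactly class-balanced by construction: one hit and one
no-hit row per accepted trial.

### Classification and evaluation

A quadratic discriminant (class-conditional Gaussians with
class-specific covariances, empirical priors) is fitted per training
split. Covariances receive a relative ridge
$\Sigma \leftarrow \Sigma + \varepsilon\,(\mathrm{tr}\,\Sigma/d)\,I$
with $\varepsilon = 10^{-6}$, enough to keep the fit defined when
integer spike counts make a class covariance singular while leaving
well-conditioned problems untouched. Exact posterior ties break to the
larger prior, then to the first class label, making predictions fully
deterministic. Evaluation is stratified five-fold cross-validation
(each fold trains on 80% of the data); folds are dealt from a seeded
shuffle within each class, so a seed pins the entire evaluation. The
reported quantities follow the confusion-matrix conventions: per-fold
error $100\,(FN+FP)/(TP+FN+TN+FP)$, their mean, accuracy
$= 100 -$ mean error, and sensitivity/specificity pooled over folds.
Session-level errors of two cases are compared with a classical one-way
ANOVA (the method statement does not say whether fold- or session-level
errors were compared; session-level matches the reported
"average errors across sessions").

### The Case B grid

Case B is evaluated over the full grid of 10 mother wavelets × 10
threshold factors ($\gamma$ evenly spaced on [0.4, 2] — the stated
range and count, with spacing the natural reading) and reports the
grid-minimum error. One cross-validation seed is shared across the
grid, so cells differ only by the denoising. Each channel is
decomposed once per wavelet; only thresholding, reconstruction and
detection are repeated per $\gamma$. Ties resolve to the first cell in
scan order (wavelets outer, $\gamma$ inner).

## The synthetic-session generator

`generate_session()` composes, per channel:

1. a piecewise-constant firing-rate profile (1 kHz grid): baseline
   `baseline_rate_hz` (default 20 Hz, a typical MUA level), multiplied
   by `hit_modulation` (default 3) in the window starting
   `premovement_onset_ms` (default −300 ms) before every hit on
   paw-mapped channels (half-strength on `paw+neck` channels, nothing
   on `neck`/`none`);
2. an inhomogeneous-Poisson spike train (thinning sampler) with a 1 ms
   dead time, matching the detector's refractory assumption;
3. a waveform rendering: a ~1 ms negative-leading biphasic template,
   each spike drawn from one of 2–5 units with jittered amplitudes —
   multi-unit activity, not a sorted single unit;
4. band-limiting to 0.8–8 kHz (zero-phase Butterworth), mirroring the
   acquisition chain at `fs = 24414` Hz;
5. additive noise: white (default $\sigma$ = 10 µV), white+pink, or
   white with sporadic broadband artifact bursts; the noise amplitude
   is multiplied by `nohit_background_gain` during paddle-retraction
   epochs, reproducing the higher background activity observed away
   from the hits.

The behavioral log contains the three-hit trials with self-paced
inter-hit gaps, the 9 s retractions, a configurable fraction of
failure-flagged trials and of sub-200 ms hit pairs (so the exclusion
rules are exercised), and everything is reproducible bit-for-bit from
the configuration seed.

What the generator does **not** emulate: biophysical waveform
diversity, electrode drift or fibrosis, the spectral content of real
chewing artifacts (bursts are amplitude-realistic, not
spectrum-realistic), or correlated noise across channels. Passing
tests therefore demonstrate that the pipeline's statistics behave as
designed under the assumed signal model, not that the absolute
accuracies transfer to any particular animal.

## Study conditions used by the validation suite

Two synthetic regimes anchor the end-to-end checks:

* **Null regime** — `hit_modulation = 1`, `nohit_background_gain = 1`:
  hit and no-hit epochs are statistically identical, and end-to-end
  accuracy must sit at chance within the binomial confidence band.
* **Low-SNR regime** — spike amplitude 10σ (100 µV over 10 µV noise),
  artifact bursts (rate 1/s, amplitude ×5, 50–300 ms) and background
  gain 1.5. The amplitude is chosen so that the pre-denoising
  SNR$_{\mathrm{estim}}$ of hit/no-hit windows lands at 8–10 dB, the
  range measured on the original recordings; the classification
  difficulty then comes from the non-stationary bursts, which flood
  the adaptive detector with false crossings. Wavelet shrinkage
  suppresses the unstructured burst energy while the spike-shaped
  coefficients survive, which is precisely the mechanism that makes
  Case B outperform Case A directionally. Absolute accuracies from the
  animal experiments are not reproducible (those recordings are not
  deposited); the validation asserts the ordering, not the values.

Simulation sizes used by the validation suite — 20 sessions of 10
trials with one paw channel for the three-case comparison, 50 null
sessions, 60 s of ground-truth signal for the detection check — are the
package's chosen trade-off between Monte-Carlo stability and a test
suite that runs in minutes.

## A worked example

```{r, eval = FALSE}
library(mudetect)

cfg <- session_config(n_trials = 10, n_channels = 2,
                      channel_categories = c("paw", "none"),
                      hit_modulation = 3, spike_amp_v = 100e-6,
                      noise_sigma = 10e-6,
                      noise_model = "white+artifact_bursts",
                      nohit_background_gain = 1.5, seed = 1)
s <- generate_session(cfg)

run_case(s$session, s$events, case_spec("A", cv_seed = 1))$eval
gr <- grid_search_caseB(s$session, s$events, case_spec("B", cv_seed = 1))
gr$min_error_pct; gr$best_wavelet; gr$best_gamma
run_case(s$session, s$events, case_spec("C", cv_seed = 1))$eval
```

## Numerical notes and limitations

* The DWT is implemented in compiled code with half-point symmetric
  extension; decomposition lengths follow
  $\lfloor (n + L - 1)/2 \rfloor$ per level and reconstruction trims
  the filter transient, so any signal length is handled exactly.
* The refractory period is enforced as $\lceil r\,f_s \rceil$ samples
  so the realised inter-spike gap is never shorter than the nominal
  1 ms.
* `estimate_noise_sigma_qq()` returns 0 (with a warning) for a constant
  window; `snr_estim()` flags an undefined SNR when the noise amplitude
  is zero.
* Degenerate ANOVA inputs (identical groups) return F = 0, p = 1
  rather than NaN.
* The quadratic discriminant is a generative classifier; with very few
  trials per session and several channels its covariance estimates are
  noisy, and cross-validated errors on small synthetic sessions are
  correspondingly variable. The validation criteria therefore aggregate
  over many seeded sessions.
* Spike timestamps are the waveform extremum, so they sit
  `peak_offset_s` (≈0.35 ms) after the template onset; ground-truth
  comparisons must add this offset, as the tests do.
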