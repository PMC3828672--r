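# mudetect

Movement detection from multi-unit intracortical recordings.

`mudetect` is an offline analysis pipeline for a basic invasive
brain–computer-interface question: can a self-paced forelimb movement
(a rat pressing a paddle, a "hit") be detected from unsorted multi-unit
activity (MUA) recorded in primary motor cortex? The package implements
the full decision chain —

1. **Wavelet denoising** — 5-level orthogonal DWT, soft threshold
   `Th = γ·σ·√(2 ln N)` with σ from a quantile–quantile noise fit,
   over 10 mother wavelets (Haar, Daubechies 2/4/6, Symlets 2/4/6,
   Coiflets 2/4/5) and 10 threshold factors γ ∈ [0.4, 2];
2. **Adaptive spike detection** — per-400 ms-window threshold
   `Thr_D = 4·σ_D`, `σ_D = median(|x|)/0.6745`, with a 1 ms refractory
   period (or a fixed manually registered threshold);
3. **Feature extraction** — spike counts of paw-mapped channels in
   three 120 ms intervals before each accepted hit ([−400, −40) ms) and
   in a background window 500 ms earlier ([−900, −540) ms);
4. **Classification** — quadratic discriminant analysis with stratified
   five-fold cross-validation; error, sensitivity, specificity and
   accuracy from the confusion matrix, one-way ANOVA across sessions.

Three analysis cases are compared end to end: **A** adaptive detection
on the raw signal, **B** denoising followed by adaptive detection
(evaluated over the full wavelet × γ grid), and **C** manual fixed
thresholds. Because the original animal recordings are not publicly
deposited, the package includes a synthetic-session generator
(`generate_session()`) reproducing the statistical structure the
analysis assumes — rate-modulated Poisson multi-unit trains with
biphasic waveforms, 0.8–8 kHz band-limiting at 24.414 kHz, stationary
and burst noise, the three-hit trial protocol with 9 s paddle
retraction — so every stage is testable against ground truth. It is a
research tool for neural-signal-processing work, not a clinical
device.

## A worked example

```r
library(mudetect)

cfg <- session_config(n_trials = 10, n_channels = 2,
                      channel_categories = c("paw", "none"),
                      hit_modulation = 3, spike_amp_v = 100e-6,
                      noise_sigma = 10e-6,
                      noise_model = "white+artifact_bursts",
                      nohit_background_gain = 1.5, seed = 1)
s <- generate_session(cfg)

ra <- run_case(s$session, s$events, case_spec("A", cv_seed = 1))
gr <- grid_search_caseB(s$session, s$events, case_spec("B", cv_seed = 1))
c(error_A = ra$eval$mean_error_pct, error_B_min = gr$min_error_pct)
```

On a batch of 20 such low-SNR sessions (`run_experiment()`, master
seed 20) the pipeline prints:

```
  case mean_error_pct sd_error_pct mean_accuracy_pct
1    A          41.75     18.44444             58.25
2    B          28.75     14.58866             71.25
3    C          44.50     16.85074             55.50
```

i.e. with heavy non-stationary burst noise, adaptive detection alone
(Case A) classifies hit vs no-hit at 58.3% accuracy, wavelet denoising
before detection (Case B, grid minimum per session) recovers 71.3%,
and a fixed manual threshold (Case C) trails both — denoising is what
makes the adaptive detector usable, and the A-vs-B difference is
significant (one-way ANOVA on session errors, p ≈ 0.018).

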