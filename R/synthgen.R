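#' Configuration of a synthetic recording session
#'
#' Describes one simulated session of the paddle-hit task: multi-channel
#' extracellular multi-unit recordings at 24.414 kHz, band-limited to
#' 0.8-8 kHz, together with the behavioral protocol (trials of three
#' consecutive self-paced hits followed by 9 s of paddle retraction).
#'
#' Channels carry a movement-mapping category from intracortical
#' microstimulation: `"paw"`, `"paw+neck"`, `"neck"` or `"none"`. Only
#' `"paw"` channels carry the full pre-movement rate elevation (starting
#' `premovement_onset_ms` before each hit); `"paw+neck"` channels carry
#' half of it; the remaining categories fire at baseline throughout.
#' Inter-trial (retraction) epochs have their broadband background
#' scaled by `nohit_background_gain`, reproducing the higher-amplitude
#' activity seen away from the hits.
#'
#' @param n_trials Number of trials (3 hits each).
#' @param fs Sampling rate in Hz (default 24414).
#' @param n_channels Number of channels.
#' @param channel_categories Character vector of per-channel categories;
#'   defaults to paw, paw, paw+neck, neck, none recycled to
#'   `n_channels`.
#' @param baseline_rate_hz Baseline multi-unit firing rate per channel.
#' @param hit_modulation Multiplicative rate gain in the pre-hit window
#'   (1 = no modulation, the null case).
#' @param premovement_onset_ms Start of the rate elevation relative to
#'   the hit, in ms (default -300, matching the lead time of forelimb
#'   muscle activity before a reach).
#' @param spike_amp_v Nominal peak spike amplitude in volts.
#' @param noise_sigma Noise standard deviation in volts.
#' @param noise_model One of `"white"`, `"white+pink"`,
#'   `"white+artifact_bursts"`.
#' @param nohit_background_gain Broadband amplitude multiplier applied
#'   in inter-trial epochs (1 = stationary background, the null case).
#' @param burst_rate_hz,burst_dur_s,burst_gain Artifact-burst parameters
#'   (bursts model only): expected rate, duration range, and amplitude
#'   ratio of burst epochs to baseline noise.
#' @param failure_fraction Fraction of trials flagged as failures
#'   (non-preferred limb or premature hit).
#' @param short_pair_fraction Fraction of trials generated with an
#'   inter-hit gap below 200 ms, to exercise the exclusion rule.
#' @param manual_bias Relative bias of the once-per-session "visually
#'   estimated" manual threshold with respect to the true 4-sigma level.
#' @param duration_s Session length in seconds; computed from the
#'   protocol timing when `NULL`.
#' @param seed Integer seed making the whole session reproducible.
#' @return Object of class `session_config`.
#' @export
session_config <- function(n_trials = 10L, fs = 24414, n_channels = 4L,
                           channel_categories = NULL,
                           baseline_rate_hz = 20, hit_modulation = 3,
                           premovement_onset_ms = -300,
                           spike_amp_v = 60e-6, noise_sigma = 10e-6,
                           noise_model = c("white", "white+pink",
                                           "white+artifact_bursts"),
                           nohit_background_gain = 1.3,
                           burst_rate_hz = 1, burst_dur_s = c(0.05, 0.3),
                           burst_gain = 5,
                           failure_fraction = 0.1,
                           short_pair_fraction = 0.05,
                           manual_bias = 0.2,
                           duration_s = NULL, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(channel_categories))
    channel_categories <- rep_len(c("paw", "paw", "paw+neck", "neck", "none"),
                                  n_channels)
  stopifnot(length(channel_categories) == n_channels,
            all(channel_categories %in% c("paw", "paw+neck", "neck", "none")),
            baseline_rate_hz > 0, hit_modulation >= 0,
            premovement_onset_ms < 0, noise_sigma >= 0, n_trials >= 1)
  if (fs <= 2 * 8000)
    stop("fs must exceed twice the 8 kHz band edge")
  # worst-case protocol footprint per trial: protraction delay + two
  # inter-hit gaps + retraction
  need <- 1.0 + n_trials * (1.2 + 2 * 0.9 + 0.05 + 9.3) + 1.0
  if (is.null(duration_s)) duration_s <- need
  else if (duration_s < need)
    stop("duration_s too short to hold ", n_trials, " trials (need >= ",
         round(need, 1), " s)")
  structure(list(n_trials = as.integer(n_trials), fs = fs,
                 n_channels = as.integer(n_channels),
                 channel_categories = channel_categories,
                 baseline_rate_hz = baseline_rate_hz,
                 hit_modulation = hit_modulation,
                 premovement_onset_ms = premovement_onset_ms,
                 spike_amp_v = spike_amp_v, noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 nohit_background_gain = nohit_background_gain,
                 burst_rate_hz = burst_rate_hz, burst_dur_s = burst_dur_s,
                 burst_gain = burst_gain,
                 failure_fraction = failure_fraction,
                 short_pair_fraction = short_pair_fraction,
                 manual_bias = manual_bias,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "session_config")
}

#' Biphasic action-potential template
#'
#' Negative-leading biphasic waveform of about 1 ms, the canonical shape
#' of an extracellular action potential (and the motivation for the
#' wavelet families used in denoising).
#'
#' @param fs Sampling rate in Hz.
#' @param amplitude Peak (negative lobe) magnitude; default 1 so the
#'   template can be scaled per spike.
#' @param duration_ms Support of the waveform in ms.
#' @return Numeric waveform; attribute `peak_offset_s` gives the time of
#'   the negative peak relative to the template onset.
#' @export
spike_template <- function(fs, amplitude = 1, duration_ms = 1.2) {
  tms <- seq(0, duration_ms, by = 1000 / fs)
  w <- -exp(-((tms - 0.35) / 0.12)^2) + 0.55 * exp(-((tms - 0.68) / 0.20)^2)
  w <- w / max(abs(w)) * amplitude
  attr(w, "peak_offset_s") <- (which.max(abs(w)) - 1L) / fs
  w
}

#' Generate an inhomogeneous-Poisson spike train with refractoriness
#'
#' Thinning sampler: homogeneous candidates at the peak rate are
#' accepted with probability rate(t)/max(rate), then a dead time of
#' `refractory_s` is enforced (later spikes in a violating pair are
#' dropped).
#'
#' @param rate Numeric vector of non-negative rate samples in Hz.
#' @param fs Sampling rate of `rate` in Hz (the rate grid, not the
#'   signal grid).
#' @param refractory_s Minimum inter-spike interval in seconds.
#' @param seed Integer seed.
#' @return Sorted spike times in seconds.
#' @export
generate_spike_train <- function(rate, fs, refractory_s = 0.001, seed = 1L) {
  if (any(rate < 0)) stop("negative rate")
  stopifnot(refractory_s >= 0, fs > 0)
  set.seed(seed)
  M <- max(rate)
  dur <- length(rate) / fs
  if (M == 0) return(numeric(0))
  n_cand <- stats::rpois(1L, M * dur)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, dur))
  r_at <- rate[pmin(floor(cand * fs) + 1L, length(rate))]
  acc <- cand[stats::runif(n_cand) < r_at / M]
  if (refractory_s > 0 && length(acc) > 1L) {
    keep <- logical(length(acc))
    last <- -Inf
    for (i in seq_along(acc)) {
      if (acc[i] - last >= refractory_s) {
        keep[i] <- TRUE
        last <- acc[i]
      }
    }
    acc <- acc[keep]
  }
  acc
}

#' Render spike times into a continuous signal
#'
#' Superposes a waveform template at each spike time (optionally scaled
#' per spike); the signal is zero elsewhere.
#'
#' @param spike_times Spike times in seconds, within `[0, duration_s)`.
#' @param template Waveform samples at the signal sampling rate.
#' @param duration_s Signal length in seconds.
#' @param fs Sampling rate in Hz.
#' @param amplitudes Optional per-spike scale factors (default 1).
#' @return Numeric signal of `round(duration_s * fs)` samples.
#' @export
render_signal <- function(spike_times, template, duration_s, fs,
                          amplitudes = NULL) {
  n <- as.integer(round(duration_s * fs))
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) >= duration_s))
    stop("spike time outside [0, duration_s)")
  if (is.null(amplitudes)) amplitudes <- rep(1, length(spike_times))
  stopifnot(length(amplitudes) == length(spike_times))
  y <- numeric(n)
  lt <- length(template)
  i0 <- as.integer(round(spike_times * fs)) + 1L
  for (k in seq_along(i0)) {
    i2 <- min(i0[k] + lt - 1L, n)
    seg <- i0[k]:i2
    y[seg] <- y[seg] + amplitudes[k] * template[seq_along(seg)]
  }
  y
}

# Pink (1/f) noise via the Kellet IIR approximation, scaled to unit SD.
.pink_noise <- function(n) {
  w <- stats::rnorm(n)
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  p <- as.numeric(stats::filter(w, filter = b, method = "convolution",
                                sides = 1))
  p[is.na(p)] <- 0
  p <- as.numeric(stats::filter(p, filter = -a[-1], method = "recursive"))
  p / stats::sd(p)
}

#' Add recording noise to a signal
#'
#' @param x Numeric signal.
#' @param noise_model `"white"` (Gaussian), `"white+pink"` (70/30 power
#'   split between white and 1/f components), or
#'   `"white+artifact_bursts"` (white noise plus sporadic broadband
#'   bursts, e.g. chewing or motion artifacts).
#' @param noise_sigma Standard deviation of the stationary component in
#'   the units of `x`.
#' @param seed Integer seed.
#' @param burst_rate_hz Expected burst rate (bursts model).
#' @param burst_dur_s Range of burst durations in seconds.
#' @param burst_gain Amplitude ratio of burst epochs to baseline noise.
#' @param fs Sampling rate in Hz (required by the bursts model to place
#'   burst epochs).
#' @return Noisy signal; for the bursts model, attribute `burst_epochs`
#'   is a data frame of burst start/end times.
#' @export
add_noise <- function(x, noise_model = "white", noise_sigma, seed = 1L,
                      burst_rate_hz = 1, burst_dur_s = c(0.05, 0.3),
                      burst_gain = 5, fs = NULL) {
  stopifnot(noise_sigma >= 0)
  if (noise_sigma == 0) return(x)
  set.seed(seed)
  n <- length(x)
  if (noise_model == "white") {
    return(x + stats::rnorm(n, 0, noise_sigma))
  }
  if (noise_model == "white+pink") {
    w <- stats::rnorm(n, 0, noise_sigma * sqrt(0.7))
    p <- .pink_noise(n) * noise_sigma * sqrt(0.3)
    return(x + w + p)
  }
  if (noise_model == "white+artifact_bursts") {
    if (is.null(fs)) stop("bursts model needs fs to place burst epochs")
    out <- x + stats::rnorm(n, 0, noise_sigma)
    dur <- n / fs
    nb <- stats::rpois(1L, burst_rate_hz * dur)
    t0 <- sort(stats::runif(nb, 0, dur))
    len <- stats::runif(nb, burst_dur_s[1], burst_dur_s[2])
    t1 <- pmin(t0 + len, dur)
    extra_sd <- noise_sigma * sqrt(burst_gain^2 - 1)
    for (b in seq_len(nb)) {
      idx <- (floor(t0[b] * fs) + 1L):min(ceiling(t1[b] * fs), n)
      out[idx] <- out[idx] + stats::rnorm(length(idx), 0, extra_sd)
    }
    attr(out, "burst_epochs") <- data.frame(t0 = t0, t1 = t1)
    return(out)
  }
  stop("unknown noise model: ", noise_model)
}

#' Generate the behavioral event log of a session
#'
#' Trials are three consecutive self-paced hits; after the third hit the
#' paddle retracts for 9 s. A configurable fraction of trials is flagged
#' as failures (non-preferred limb or premature hit) and a configurable
#' fraction contains an inter-hit gap below 200 ms.
#'
#' @param config A [session_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return Data frame of events with columns `time_s`, `event_type`
#'   (`protract`, `hit`, `retract`), `trial_id`, `accepted_flag`,
#'   `failure_reason`.
#' @export
generate_behavior <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "session_config"))
  set.seed(seed)
  n <- config$n_trials
  fail <- stats::runif(n) < config$failure_fraction
  reason <- ifelse(fail,
                   sample(c("non_preferred_limb", "premature_hit"), n,
                          replace = TRUE),
                   "")
  shortpair <- !fail & stats::runif(n) < config$short_pair_fraction
  rows <- vector("list", n)
  t <- 1.0
  for (i in seq_len(n)) {
    d1 <- stats::runif(1, 0.6, 1.2)
    g2 <- if (shortpair[i]) stats::runif(1, 0.08, 0.18)
          else stats::runif(1, 0.35, 0.9)
    g3 <- stats::runif(1, 0.35, 0.9)
    h <- t + d1 + c(0, g2, g2 + g3)
    retract <- h[3] + 0.05
    rows[[i]] <- data.frame(
      time_s = c(t, h, retract),
      event_type = c("protract", "hit", "hit", "hit", "retract"),
      trial_id = i,
      accepted_flag = !fail[i],
      failure_reason = reason[i])
    t <- retract + 9.0 + stats::runif(1, 0, 0.3)
  }
  events <- do.call(rbind, rows)
  if (max(events$time_s) + 9 > config$duration_s)
    stop("protocol does not fit in duration_s")
  events
}

#' Generate a complete synthetic session
#'
#' Composes behavior, per-channel rate-modulated multi-unit spike
#' trains, waveform rendering, acquisition band-limiting (0.8-8 kHz)
#' and additive noise into a reproducible session with ground truth.
#'
#' Each channel superposes 2-5 units with jittered amplitudes on a
#' shared rate profile. Pre-hit rate elevation applies to `"paw"`
#' channels (half-strength on `"paw+neck"`); the noise background is
#' scaled by `nohit_background_gain` during paddle-retraction epochs.
#'
#' @param config A [session_config()].
#' @return List with `session` (class `recording_session`: `fs`,
#'   `signals`, `channel_categories`, `manual_thresholds`, `band`),
#'   `events` (behavioral log data frame) and `truth` (per-channel true
#'   spike times and rate profiles, the template, and the true noise
#'   sigma).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L + 3L * config$n_channels)
  events <- generate_behavior(config, seed = seeds[1])
  fs <- config$fs
  dur <- config$duration_s
  n <- as.integer(round(dur * fs))
  rate_fs <- 1000
  n_rate <- as.integer(round(dur * rate_fs))
  hits <- events$time_s[events$event_type == "hit"]
  onset_s <- config$premovement_onset_ms / 1000  # negative

  # retraction (inter-trial) epochs: before the first protraction,
  # between each retract and the next protract, and after the last
  # retract
  prot <- events$time_s[events$event_type == "protract"]
  retr <- events$time_s[events$event_type == "retract"]
  epochs <- data.frame(t0 = c(0, retr), t1 = c(prot, dur))

  tmpl <- spike_template(fs)
  set.seed(seeds[2])
  k_units <- sample(2:5, config$n_channels, replace = TRUE)

  signals <- vector("list", config$n_channels)
  true_spikes <- vector("list", config$n_channels)
  rate_profiles <- vector("list", config$n_channels)
  for (ch in seq_len(config$n_channels)) {
    cat_gain <- switch(config$channel_categories[ch],
                       "paw" = config$hit_modulation,
                       "paw+neck" = 1 + (config$hit_modulation - 1) / 2,
                       1)
    rate <- rep(config$baseline_rate_hz, n_rate)
    if (cat_gain != 1) {
      for (h in hits) {
        i0 <- max(1L, floor((h + onset_s) * rate_fs) + 1L)
        i1 <- min(n_rate, ceiling(h * rate_fs))
        rate[i0:i1] <- config$baseline_rate_hz * cat_gain
      }
    }
    st <- generate_spike_train(rate, rate_fs, refractory_s = 0.001,
                               seed = seeds[2 + ch])
    st <- st[st < dur - length(tmpl) / fs]
    set.seed(seeds[2 + config$n_channels + ch])
    unit_amp <- config$spike_amp_v * stats::runif(k_units[ch], 0.7, 1.3)
    amps <- unit_amp[sample.int(k_units[ch], length(st), replace = TRUE)]
    clean <- render_signal(st, tmpl, dur, fs, amplitudes = amps)
    clean <- .bandlimit(clean, fs)
    noise <- add_noise(numeric(n), config$noise_model, config$noise_sigma,
                       seed = seeds[2 + 2 * config$n_channels + ch],
                       burst_rate_hz = config$burst_rate_hz,
                       burst_dur_s = config$burst_dur_s,
                       burst_gain = config$burst_gain, fs = fs)
    if (config$nohit_background_gain != 1) {
      for (e in seq_len(nrow(epochs))) {
        if (epochs$t1[e] <= epochs$t0[e]) next
        idx <- (floor(epochs$t0[e] * fs) + 1L):min(n, ceiling(epochs$t1[e] * fs))
        noise[idx] <- noise[idx] * config$nohit_background_gain
      }
    }
    signals[[ch]] <- clean + as.numeric(noise)
    true_spikes[[ch]] <- st
    rate_profiles[[ch]] <- rate
  }

  set.seed(seeds[2] + 1L)
  manual <- 4 * config$noise_sigma *
    (1 + config$manual_bias + stats::runif(config$n_channels, -0.05, 0.05))

  session <- structure(list(fs = fs, signals = signals,
                            channel_categories = config$channel_categories,
                            manual_thresholds = manual,
                            band = c(800, 8000)),
                       class = "recording_session")
  truth <- list(spike_times = true_spikes, rate_profiles = rate_profiles,
                rate_fs = rate_fs, template = tmpl * config$spike_amp_v,
                noise_sigma_true = config$noise_sigma,
                retraction_epochs = epochs)
  list(session = session, events = events, truth = truth)
}

# Acquisition band-limiting: 0.8-8 kHz zero-phase Butterworth band-pass.
.bandlimit <- function(x, fs, band = c(800, 8000)) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}
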