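# Shared fixtures, built once per test run.

# Small clean event log: n trials of 3 hits, none flagged.
make_clean_events <- function(n_trials, gap = c(0.5, 0.6)) {
  rows <- lapply(seq_len(n_trials), function(i) {
    t0 <- 1 + (i - 1) * 12
    h <- t0 + 0.8 + c(0, gap[1], gap[1] + gap[2])
    data.frame(time_s = c(t0, h, h[3] + 0.05),
               event_type = c("protract", "hit", "hit", "hit", "retract"),
               trial_id = i, accepted_flag = TRUE, failure_reason = "")
  })
  do.call(rbind, rows)
}

# Spike train object with given times (for feature-counting tests).
make_train <- function(times, channel = 1L, fs = 24414) {
  structure(list(channel = channel, spike_times = sort(times),
                 thresholds = numeric(0), fs = fs,
                 config = detect_config()),
            class = "spike_train")
}

# Greedy one-to-one matching of detected to true event times within a
# tolerance; returns F1 plus the counts it is built from.
match_f1 <- function(detected, truth, tol_s = 5e-4) {
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol_s)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, tp = tp, fp = fp, fn = fn)
}

# One small modulated session, generated once and reused read-only.
cached_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- session_config(n_trials = 6, n_channels = 2,
                            channel_categories = c("paw", "paw"),
                            baseline_rate_hz = 20, hit_modulation = 3,
                            spike_amp_v = 80e-6, noise_sigma = 10e-6,
                            noise_model = "white", seed = 42)
      cache <<- generate_session(cfg)
    }
    cache
  }
})
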