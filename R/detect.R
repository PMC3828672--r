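#' Spike-detection configuration
#'
#' @param mode `"adaptive"` recomputes the threshold per consecutive
#'   window from the median-based noise estimate; `"manual"` uses one
#'   fixed threshold for the whole recording.
#' @param window_s Window length in seconds for adaptive threshold
#'   recomputation (default 0.400).
#' @param refractory_s Minimum interval between detected spikes in
#'   seconds (default 0.001).
#' @param polarity Which excursions count: `"absolute"` (default),
#'   `"negative"` or `"positive"`.
#' @param manual_threshold Threshold magnitude in volts (manual mode
#'   only).
#' @return Object of class `detect_config`.
#' @export
detect_config <- function(mode = c("adaptive", "manual"),
                          window_s = 0.400, refractory_s = 0.001,
                          polarity = c("absolute", "negative", "positive"),
                          manual_threshold = NULL) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  stopifnot(window_s > 0, refractory_s >= 0)
  if (mode == "manual" && is.null(manual_threshold))
    stop("manual mode requires manual_threshold")
  if (!is.null(manual_threshold))
    stopifnot(is.numeric(manual_threshold), manual_threshold >= 0)
  structure(list(mode = mode, window_s = window_s,
                 refractory_s = refractory_s, polarity = polarity,
                 manual_threshold = manual_threshold),
            class = "detect_config")
}

#' Adaptive detection threshold of a data window
#'
#' Thr_D = 4 sigma_D with sigma_D = median(|x|) / 0.6745. The median
#' keeps the threshold anchored to the noise floor even when the window
#' contains many or large action potentials.
#'
#' @param window Numeric vector (non-empty).
#' @return Threshold in the units of the window.
#' @export
adaptive_threshold <- function(window) {
  4 * estimate_noise_sigma_mad(window)
}

#' Detect multi-unit spikes by thresholding
#'
#' Scans the signal for threshold excursions of the configured polarity.
#' In adaptive mode the threshold is recomputed for every consecutive
#' non-overlapping window (the trailing partial window uses its own
#' samples). A spike is timestamped at the extremum within 1 ms of the
#' first threshold crossing; crossings closer than the refractory
#' period to the previously kept spike are discarded.
#'
#' @param x Numeric signal vector (volts).
#' @param fs Sampling rate in Hz.
#' @param config A [detect_config()].
#' @param channel Channel identifier carried into the result.
#' @return Object of class `spike_train`: list with `channel`,
#'   `spike_times` (sorted seconds, sample k at time (k-1)/fs),
#'   `thresholds` (per-window Thr_D trace, volts) and the config.
#' @export
detect_spikes <- function(x, fs, config = detect_config(), channel = 1L) {
  stopifnot(is.numeric(x), is.numeric(fs), fs > 0,
            inherits(config, "detect_config"))
  win <- max(1L, as.integer(round(config$window_s * fs)))
  if (length(x) < 1L) stop("empty signal")
  n <- length(x)
  nw <- max(1L, ceiling(n / win))
  if (config$mode == "adaptive") {
    thr <- .window_mad_thresholds(x, win)
  } else {
    thr <- rep(config$manual_threshold, nw)
  }
  v <- switch(config$polarity,
              absolute = abs(x),
              negative = -x,
              positive = x)
  search <- max(1L, as.integer(round(0.001 * fs)))
  # ceiling so the enforced sample gap is never shorter than the
  # refractory period in seconds
  refr <- as.integer(ceiling(config$refractory_s * fs))
  idx <- .detect_scan(v, thr, win, search, refr)
  structure(list(channel = channel, spike_times = idx / fs,
                 thresholds = thr, config = config, fs = fs),
            class = "spike_train")
}

#' Count spikes in a half-open interval [t0, t1)
#'
#' @param train A `spike_train` (or any list with sorted `spike_times`).
#' @param t0,t1 Interval bounds in seconds, t0 < t1 (t0 == t1 gives 0).
#' @return Integer count.
#' @export
count_in_interval <- function(train, t0, t1) {
  stopifnot(t0 <= t1)
  st <- train$spike_times
  sum(st >= t0 & st < t1)
}
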