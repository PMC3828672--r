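#' Spike-count window specification
#'
#' Defines the three contiguous 120 ms counting intervals (Int1-Int3)
#' for the "hit" epoch and for the "no-hit" epoch, both anchored to the
#' hit timestamp (paddle closure). The default `"offset40"` anchoring
#' places the hit span at [-400, -40) ms, honoring the observation that
#' forelimb muscle activity leads the movement by about 300 ms and
#' continues up to 50 ms after; `"flush"` places it at [-360, 0) ms. The
#' no-hit span mirrors the hit span shifted 500 ms earlier, i.e.
#' [-900, -540) ms under the default anchoring.
#'
#' @param anchor `"offset40"` (default) or `"flush"`.
#' @return Object of class `window_spec` with `hit_edges` and
#'   `nohit_edges`: vectors of 4 bin edges in seconds relative to the
#'   hit.
#' @export
window_spec <- function(anchor = c("offset40", "flush")) {
  anchor <- match.arg(anchor)
  hit <- if (anchor == "offset40") seq(-0.400, -0.040, by = 0.120)
         else seq(-0.360, 0, by = 0.120)
  structure(list(anchor = anchor, hit_edges = hit,
                 nohit_edges = hit - 0.5),
            class = "window_spec")
}

#' Select accepted trials from a behavioral log
#'
#' Applies the acceptance rules: a trial must consist of three hits,
#' must not be flagged as a failure (non-preferred limb, premature
#' hit), and must not contain two consecutive hits less than 200 ms
#' apart. Only the first hit of each accepted trial is retained.
#'
#' @param events Behavioral log data frame (see [generate_behavior()]).
#' @param min_gap_s Minimum allowed inter-hit gap (default 0.2).
#' @return Data frame with `trial_id` and `hit_time` (the first hit of
#'   each accepted trial), possibly empty.
#' @export
select_trials <- function(events, min_gap_s = 0.2) {
  validate_events(events)
  out <- lapply(split(events, events$trial_id), function(tr) {
    h <- sort(tr$time_s[tr$event_type == "hit"])
    if (length(h) != 3L) return(NULL)
    if (!all(tr$accepted_flag)) return(NULL)
    if (any(diff(h) < min_gap_s)) return(NULL)
    data.frame(trial_id = tr$trial_id[1], hit_time = h[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(trial_id = integer(0), hit_time = numeric(0)))
  out[order(out$hit_time), , drop = FALSE]
}

#' Extract hit and no-hit spike-count features for one trial
#'
#' Counts spikes of each supplied channel in the three 120 ms intervals
#' of the hit window and of the no-hit window, both relative to the
#' trial's first hit. Intervals are half-open `[t0, t1)` so the three
#' bins partition their span.
#'
#' @param trains List of `spike_train` objects (one per selected
#'   channel).
#' @param hit_time First-hit timestamp of the trial in seconds; must be
#'   at least 0.9 s into the recording so the no-hit window exists.
#' @param windows A [window_spec()].
#' @return List with `hit` and `nohit`: integer matrices (channels x 3
#'   intervals).
#' @export
extract_features <- function(trains, hit_time, windows = window_spec()) {
  stopifnot(inherits(windows, "window_spec"))
  if (hit_time + min(windows$nohit_edges) < 0)
    stop("no-hit window precedes recording start")
  count_bins <- function(edges) {
    t(vapply(trains, function(tr) {
      vapply(1:3, function(b) {
        count_in_interval(tr, hit_time + edges[b], hit_time + edges[b + 1])
      }, numeric(1))
    }, numeric(3)))
  }
  list(hit = count_bins(windows$hit_edges),
       nohit = count_bins(windows$nohit_edges))
}

#' Build the balanced classification dataset of a session
#'
#' One "hit" and one "no-hit" feature row per accepted trial, using only
#' the channels mapped to paw movements. Columns are ordered
#' channel-major: channel 1 Int1..Int3, channel 2 Int1..Int3, ...
#'
#' @param trains List of `spike_train` objects for all channels, in
#'   channel order.
#' @param events Behavioral log data frame.
#' @param channel_categories Per-channel movement-mapping categories.
#' @param windows A [window_spec()].
#' @return List with `x` (numeric matrix, 2 rows per accepted trial),
#'   `y` (factor with levels `hit`, `nohit`) and `trial_id`.
#' @export
build_dataset <- function(trains, events, channel_categories,
                          windows = window_spec()) {
  paw <- which(channel_categories == "paw")
  if (length(paw) == 0L) stop("no paw-category channels to build features from")
  stopifnot(length(trains) == length(channel_categories))
  sel <- select_trials(events)
  usable <- sel$hit_time + min(windows$nohit_edges) >= 0
  if (any(!usable))
    message(sum(!usable), " trial(s) dropped: window precedes recording start")
  sel <- sel[usable, , drop = FALSE]
  if (nrow(sel) < 2L) stop("fewer than 2 accepted trials")
  rows_hit <- matrix(0, nrow(sel), 3L * length(paw))
  rows_nohit <- rows_hit
  for (i in seq_len(nrow(sel))) {
    f <- extract_features(trains[paw], sel$hit_time[i], windows)
    rows_hit[i, ] <- as.vector(t(f$hit))
    rows_nohit[i, ] <- as.vector(t(f$nohit))
  }
  colnames(rows_hit) <- colnames(rows_nohit) <-
    paste0("ch", rep(paw, each = 3), "_int", rep(1:3, length(paw)))
  x <- rbind(rows_hit, rows_nohit)
  y <- factor(rep(c("hit", "nohit"), each = nrow(sel)),
              levels = c("hit", "nohit"))
  list(x = x, y = y, trial_id = rep(sel$trial_id, 2L))
}
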