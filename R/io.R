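#' Write / read a recording session container
#'
#' A session directory holds one little-endian 32-bit float binary file
#' per channel (`chNN.f32`, volts) plus a JSON sidecar `session.json`
#' with the sampling rate, channel categories, manual thresholds, band
#' and per-channel sample counts.
#'
#' @param session A `recording_session` (see [generate_session()]).
#' @param path Session directory (created if missing).
#' @return `write_session` returns `path` invisibly; `read_session`
#'   returns a validated `recording_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nch <- length(session$signals)
  files <- sprintf("ch%02d.f32", seq_len(nch))
  for (ch in seq_len(nch)) {
    con <- file(file.path(path, files[ch]), "wb")
    writeBin(as.numeric(session$signals[[ch]]), con, size = 4L,
             endian = "little")
    close(con)
  }
  sidecar <- list(fs = session$fs, n_channels = nch,
                  channel_categories = session$channel_categories,
                  manual_thresholds = session$manual_thresholds,
                  band = session$band, units = "volts",
                  n_samples = vapply(session$signals, length, integer(1)),
                  files = files)
  jsonlite::write_json(sidecar, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  sc_path <- file.path(path, "session.json")
  if (!file.exists(sc_path)) stop("missing sidecar session.json")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (f in c("fs", "n_channels", "channel_categories", "n_samples", "files"))
    if (is.null(sc[[f]])) stop("sidecar missing field: ", f)
  if (sc$fs <= 0) stop("sidecar field fs must be positive")
  nch <- sc$n_channels
  if (length(sc$files) != nch || length(sc$n_samples) != nch ||
      length(sc$channel_categories) != nch)
    stop("sidecar per-channel fields inconsistent with n_channels")
  signals <- vector("list", nch)
  for (ch in seq_len(nch)) {
    fp <- file.path(path, sc$files[ch])
    if (!file.exists(fp)) stop("missing channel file: ", sc$files[ch])
    expect_bytes <- 4 * sc$n_samples[ch]
    if (file.info(fp)$size != expect_bytes)
      stop("channel ", sc$files[ch], ": expected ", expect_bytes,
           " bytes, found ", file.info(fp)$size)
    con <- file(fp, "rb")
    signals[[ch]] <- readBin(con, numeric(), n = sc$n_samples[ch],
                             size = 4L, endian = "little")
    close(con)
  }
  if (length(unique(sc$n_samples)) > 1L)
    stop("channels differ in length")
  manual <- sc$manual_thresholds
  if (!is.null(manual) && all(is.na(manual))) manual <- NULL
  structure(list(fs = sc$fs, signals = signals,
                 channel_categories = sc$channel_categories,
                 manual_thresholds = manual,
                 band = sc$band),
            class = "recording_session")
}

#' Validate a behavioral event log
#'
#' Checks the column set, event types, strictly increasing timestamps
#' and that every accepted trial groups exactly three hits.
#'
#' @param events Event data frame.
#' @return The validated data frame, invisibly.
#' @export
validate_events <- function(events) {
  need <- c("time_s", "event_type", "trial_id", "accepted_flag",
            "failure_reason")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event log missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(events$event_type), c("protract", "hit", "retract"))
  if (length(bad)) stop("unknown event_type: ", paste(bad, collapse = ", "))
  if (any(diff(events$time_s) <= 0)) stop("event times not strictly increasing")
  hits <- table(events$trial_id[events$event_type == "hit"])
  acc <- tapply(events$accepted_flag, events$trial_id, all)
  if (any(acc[names(hits)] & hits != 3L))
    stop("accepted trial without exactly 3 hits")
  invisible(events)
}

#' Write / read a behavioral event log CSV
#'
#' Columns: `time_s`, `event_type` (protract/hit/retract), `trial_id`,
#' `accepted_flag`, `failure_reason`. UTF-8, header row, '.' decimal.
#'
#' @param events Event data frame.
#' @param path CSV file path.
#' @return `write_events` returns `path` invisibly; `read_events` a
#'   validated data frame.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.csv(events, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(failure_reason = "character"))
  ev$failure_reason[is.na(ev$failure_reason)] <- ""
  validate_events(ev)
  ev
}

#' Write / read detected spike times CSV
#'
#' Columns: `channel`, `spike_time_s`, `threshold_at_event` (the
#' detection threshold of the window containing the event, volts).
#'
#' @param trains List of `spike_train` objects.
#' @param path CSV file path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` a
#'   data frame sorted by channel and time.
#' @export
write_spikes <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (length(tr$spike_times) == 0L)
      return(data.frame(channel = integer(0), spike_time_s = numeric(0),
                        threshold_at_event = numeric(0)))
    win <- max(1L, as.integer(round(tr$config$window_s * tr$fs)))
    w <- pmin(floor(tr$spike_times * tr$fs / win) + 1L,
              length(tr$thresholds))
    data.frame(channel = tr$channel, spike_time_s = tr$spike_times,
               threshold_at_event = tr$thresholds[w])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  sp <- utils::read.csv(path)
  need <- c("channel", "spike_time_s", "threshold_at_event")
  miss <- setdiff(need, names(sp))
  if (length(miss)) stop("spike table missing column(s): ",
                         paste(miss, collapse = ", "))
  sp[order(sp$channel, sp$spike_time_s), , drop = FALSE]
}

#' Write / read a per-trial feature table CSV
#'
#' Long format, one row per trial, label and channel:
#' `trial_id, label, channel, int1, int2, int3`.
#'
#' @param dataset Output of [build_dataset()].
#' @param path CSV file path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   the data frame.
#' @export
write_features <- function(dataset, path) {
  cn <- colnames(dataset$x)
  chans <- unique(sub("_int[123]$", "", cn))
  rows <- lapply(seq_len(nrow(dataset$x)), function(i) {
    do.call(rbind, lapply(chans, function(chn) {
      v <- dataset$x[i, paste0(chn, "_int", 1:3)]
      data.frame(trial_id = dataset$trial_id[i],
                 label = as.character(dataset$y[i]),
                 channel = as.integer(sub("^ch", "", chn)),
                 int1 = v[1], int2 = v[2], int3 = v[3])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  fx <- utils::read.csv(path)
  need <- c("trial_id", "label", "channel", "int1", "int2", "int3")
  miss <- setdiff(need, names(fx))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(fx$label %in% c("hit", "nohit"))) stop("unknown label in table")
  fx
}
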