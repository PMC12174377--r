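# Conditioning of raw recordings, force-trace onset detection, epoching and
# automated trial rejection.

#' Container for epoched data
#'
#' @param data Numeric array, trials x channels x samples, in uV.
#' @param epoch_times Time axis in ms: relative to segment start for resting
#'   epochs, relative to press onset for event epochs.
#' @param fs Sampling rate in Hz.
#' @param kind `"resting"` or `"event"`.
#' @param channel_names Channel labels.
#' @param kept Logical per trial (defaults to all `TRUE`).
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, epoch_times, fs, kind, channel_names,
                      kept = rep(TRUE, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(epoch_times),
            dim(data)[2] == length(channel_names),
            length(kept) == dim(data)[1])
  kind <- match.arg(kind, c("resting", "event"))
  structure(list(data = data, epoch_times = epoch_times, fs = fs,
                 kind = kind, channel_names = channel_names, kept = kept,
                 status = "ok"),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set:%s> %d trials (%d kept) x %d ch x %d samples @ %g Hz [%s]\n",
              x$kind, dim(x$data)[1], sum(x$kept), dim(x$data)[2],
              dim(x$data)[3], x$fs, x$status))
  invisible(x)
}

# zero-phase Butterworth section applied forward-backward
.filtfilt_butter <- function(x, n, W, type) {
  bf <- signal::butter(n, W, type = type)
  signal::filtfilt(bf, x)
}

# RBJ biquad notch, applied zero-phase; Q defaults to 30
.filtfilt_notch <- function(x, f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(b / a[1], a / a[1], x)
}

#' Condition a raw recording
#'
#' Band-pass 0.5-95 Hz and 50 Hz notch, both applied zero-phase
#' (forward-backward) at the native rate, then integer decimation to
#' 500 Hz. Event sample indices are mapped to the new rate.
#'
#' @param raw A [raw_recording()] with `fs >= 1000`.
#' @param fs_out Target rate in Hz (default 500; must divide `raw$fs`).
#' @param band Pass band in Hz (default `c(0.5, 95)`).
#' @param notch_hz Mains frequency to notch out (default 50).
#' @return A [raw_recording()] at `fs_out`.
#' @export
condition_raw <- function(raw, fs_out = 500, band = c(0.5, 95),
                          notch_hz = 50) {
  stopifnot(inherits(raw, "raw_recording"))
  if (raw$fs < 1000) stop("condition_raw expects a native rate >= 1000 Hz")
  dec <- raw$fs / fs_out
  if (dec != round(dec)) stop("fs_out must divide the native rate")
  if (fs_out < 2 * band[2]) stop("target rate below 2x the upper pass edge")
  out <- raw$data
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    x <- .filtfilt_butter(x, 4, band[2] / (raw$fs / 2), "low")
    x <- .filtfilt_butter(x, 2, band[1] / (raw$fs / 2), "high")
    x <- .filtfilt_notch(x, notch_hz, raw$fs)
    out[ch, ] <- x
  }
  keep <- seq(1, ncol(out), by = dec)
  events <- raw$events
  if (nrow(events)) {
    events$sample <- as.integer(round((events$sample - 1) / dec) + 1)
  }
  raw_recording(out[, keep, drop = FALSE], fs_out, raw$channel_names, events)
}

#' Detect press onsets from a force trace
#'
#' A press onset is the first sample at which the force exceeds the
#' threshold; subsequent crossings within the refractory window belong to
#' the same press. Indices are converted from the force-trace rate to the
#' EEG rate by nearest-sample mapping `round(i * eeg_fs / force_fs)`.
#'
#' @param force A `force_trace` (list with `samples` in N and `fs`).
#' @param threshold Threshold in newtons (default 0.5); must exceed the
#'   sensor noise floor.
#' @param refractory_s Dead time after each onset in seconds (default 2).
#' @param eeg_fs EEG sampling rate the indices are mapped to (default 500).
#' @return Integer vector of onset sample indices at `eeg_fs`.
#' @export
detect_movement_onsets <- function(force, threshold = 0.5,
                                   refractory_s = 2, eeg_fs = 500) {
  x <- force$samples
  if (!length(x)) return(integer())
  if (any(!is.finite(x))) stop("force trace contains non-finite values")
  stopifnot(threshold > 0, refractory_s >= 0)
  above <- which(x > threshold)
  if (!length(above)) return(integer())
  refr <- refractory_s * force$fs
  onsets <- integer()
  next_ok <- -Inf
  for (i in above) {
    if (i >= next_ok) {
      onsets <- c(onsets, i)
      next_ok <- i + refr
    }
  }
  as.integer(round(onsets * eeg_fs / force$fs))
}

#' Cut a conditioned recording into epochs
#'
#' Resting recordings are divided into consecutive non-overlapping 2000 ms
#' segments. Event recordings yield one epoch per onset spanning -2500 to
#' 4500 ms relative to the press; onsets too close to the recording edges
#' are dropped with a warning.
#'
#' @param raw A conditioned [raw_recording()].
#' @param kind `"resting"` or `"event"`.
#' @param onsets Onset sample indices at `raw$fs` (event kind only).
#' @param resting_len_ms,event_window_ms Segment length / event window.
#' @return An [epoch_set()].
#' @export
make_epochs <- function(raw, kind = c("resting", "event"), onsets = NULL,
                        resting_len_ms = 2000,
                        event_window_ms = c(-2500, 4500)) {
  kind <- match.arg(kind)
  fs <- raw$fs
  n <- ncol(raw$data)
  if (kind == "resting") {
    len <- round(resting_len_ms / 1000 * fs)
    n_ep <- n %/% len
    if (n_ep < 1) stop("recording shorter than one resting segment")
    data <- array(0, c(n_ep, nrow(raw$data), len))
    for (e in seq_len(n_ep)) {
      data[e, , ] <- raw$data[, ((e - 1) * len + 1):(e * len)]
    }
    times <- (seq_len(len) - 1) / fs * 1000
    return(epoch_set(data, times, fs, "resting", raw$channel_names))
  }
  if (is.null(onsets) || !length(onsets)) stop("event epoching requires onsets")
  pre <- round(-event_window_ms[1] / 1000 * fs)
  post <- round(event_window_ms[2] / 1000 * fs)
  ok <- onsets - pre >= 1 & onsets + post - 1 <= n
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) too close to the recording edge; dropped")
    onsets <- onsets[ok]
  }
  if (!length(onsets)) stop("no onset admits the full epoch window")
  len <- pre + post
  data <- array(0, c(length(onsets), nrow(raw$data), len))
  for (e in seq_along(onsets)) {
    data[e, , ] <- raw$data[, (onsets[e] - pre):(onsets[e] + post - 1)]
  }
  times <- (seq_len(len) - 1 - pre) / fs * 1000
  epoch_set(data, times, fs, "event", raw$channel_names)
}

#' Flag bad epochs by peak-to-peak amplitude
#'
#' Automated, reproducible stand-in for visual trial screening: any trial
#' whose peak-to-peak amplitude on any channel exceeds the threshold is
#' flagged `kept = FALSE`. Datasets with fewer than 11 kept trials are
#' marked `excluded`; datasets below `min_trials` (default 20, the
#' recommended minimum) are marked `below_recommended`.
#'
#' @param epochs An [epoch_set()].
#' @param ptp_threshold Peak-to-peak rejection threshold in uV (default 200).
#' @param min_trials Recommended minimum number of kept trials (default 20).
#' @param exclude_below Hard exclusion bound (default 11).
#' @return The epoch set with updated `kept` flags and `status` one of
#'   `"ok"`, `"below_recommended"`, `"excluded"`. Trial order is unchanged.
#' @export
reject_epochs <- function(epochs, ptp_threshold = 200, min_trials = 20,
                          exclude_below = 11) {
  stopifnot(inherits(epochs, "epoch_set"), ptp_threshold > 0)
  ptp <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  kept <- apply(ptp, 1, max) <= ptp_threshold
  epochs$kept <- kept & epochs$kept
  n_kept <- sum(epochs$kept)
  if (n_kept == 0) {
    stop("all trials rejected (max peak-to-peak ",
         round(max(ptp), 1), " uV, threshold ", ptp_threshold, " uV)")
  }
  epochs$status <- if (n_kept < exclude_below) {
    warning("dataset excluded: only ", n_kept, " kept trials (< ",
            exclude_below, ")")
    "excluded"
  } else if (n_kept < min_trials) {
    warning("dataset below recommended minimum: ", n_kept, " kept trials")
    "below_recommended"
  } else "ok"
  epochs
}
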