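# Scalar features: per-trial peak beta frequency, endogenous-exogenous
# frequency difference, and percent-change of event-related power.

#' Peak beta frequency of one trial's time-frequency map
#'
#' The map is averaged over the period's time points first; the peak is the
#' beta-band (13-30 Hz) frequency of the most negative period-mean value
#' for ERD periods (pre-movement, movement) or the most positive for the
#' ERS period (post-movement). Ties resolve to the lower frequency.
#'
#' @param tf_map Numeric matrix, freqs x times, on the dB-baseline scale.
#' @param freqs_hz,times_ms Axes of `tf_map`.
#' @param period `c(lo, hi)` window in ms.
#' @param kind `"erd"` (minimum) or `"ers"` (maximum).
#' @param beta_hz Beta band limits (default `c(13, 30)`).
#' @return Peak frequency in Hz. An all-equal map returns the lowest beta
#'   frequency with a warning.
#' @export
peak_beta_frequency <- function(tf_map, freqs_hz, times_ms, period,
                                kind = c("erd", "ers"),
                                beta_hz = c(13, 30)) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(tf_map), nrow(tf_map) == length(freqs_hz),
            ncol(tf_map) == length(times_ms))
  fsel <- which(freqs_hz >= beta_hz[1] & freqs_hz <= beta_hz[2])
  if (!length(fsel)) stop("no beta-band bins on the frequency axis")
  tsel <- which(times_ms >= period[1] & times_ms <= period[2])
  if (!length(tsel)) stop("period contains no time points")
  spec <- rowMeans(tf_map[fsel, tsel, drop = FALSE])
  if (diff(range(spec)) < .Machine$double.eps * 100) {
    warning("flat period-mean spectrum; returning the lowest beta frequency")
    return(freqs_hz[fsel[1]])
  }
  pick <- if (kind == "erd") which.min(spec) else which.max(spec)
  freqs_hz[fsel[pick]]
}

#' Endogenous-exogenous frequency difference
#'
#' Peak beta frequency minus the stimulation frequency (20 Hz).
#'
#' @param peak_hz Peak beta frequency in Hz.
#' @param stim_hz Stimulation frequency (default 20).
#' @return Difference in Hz.
#' @export
endo_exo_difference <- function(peak_hz, stim_hz = 20) peak_hz - stim_hz

#' Per-trial peak beta table for an event-related tensor
#'
#' Applies [peak_beta_frequency()] to every kept trial, ROI and movement
#' period (ERD rule for pre-movement/movement, ERS rule for post-movement).
#'
#' @param db_power A `db_baseline` [power_tensor()].
#' @param periods A [period_spec()].
#' @param stim_hz Stimulation frequency for the difference column.
#' @return Data frame with `trial`, `region`, `period`, `peak_hz`,
#'   `endo_exo_diff_hz`.
#' @export
peak_beta_table <- function(db_power, periods = period_spec(), stim_hz = 20) {
  stopifnot(inherits(db_power, "power_tensor"),
            db_power$scale == "db_baseline")
  kinds <- c(pre_movement = "erd", movement = "erd", post_movement = "ers")
  d <- dim(db_power$values)
  rows <- list()
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      m <- db_power$values[tr, ch, , ]
      for (p in names(kinds)) {
        pk <- peak_beta_frequency(m, db_power$freq_axis, db_power$time_axis,
                                  periods[[p]], kinds[[p]])
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, region = db_power$channels[ch], period = p,
          peak_hz = pk, endo_exo_diff_hz = endo_exo_difference(pk, stim_hz),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent-change in event-related power between two measurement blocks
#'
#' Element-wise `100 * (b - a) / a` on trial-averaged linear
#' (baseline-ratio) power maps sharing the same axes. Elements where the
#' reference map falls below `eps` are set to `NA` and counted.
#'
#' @param map_a,map_b Numeric matrices (freqs x times), linear scale.
#' @param eps Reference floor below which the change is undefined.
#' @return Matrix of percent changes, with attribute `n_floored`.
#' @export
delta_power <- function(map_a, map_b, eps = 1e-12) {
  stopifnot(is.matrix(map_a), identical(dim(map_a), dim(map_b)))
  out <- 100 * (map_b - map_a) / map_a
  floored <- which(map_a < eps)
  if (length(floored)) {
    tb_log(length(floored), " pixels below the delta-power floor; set NA")
    out[floored] <- NA_real_
  }
  attr(out, "n_floored") <- length(floored)
  out
}

#' Trial-averaged linear power map restricted to a period
#'
#' Convenience extractor for the cluster-correlation stage: averages a
#' linear [power_tensor()] over kept trials and returns the freqs x times
#' map of one ROI restricted to a period window.
#'
#' @param power Linear-scale [power_tensor()] (e.g. [baseline_ratio()]).
#' @param region ROI label (`"C3"` or `"C4"`).
#' @param period `c(lo, hi)` ms window.
#' @param kept Optional logical vector of trials to include.
#' @return Numeric matrix freqs x times with `freqs_hz`/`times_ms` attributes.
#' @export
trial_average_map <- function(power, region, period, kept = NULL) {
  stopifnot(inherits(power, "power_tensor"))
  ch <- match(region, power$channels)
  if (is.na(ch)) stop("unknown region: ", region)
  tsel <- which(power$time_axis >= period[1] & power$time_axis <= period[2])
  trials <- if (is.null(kept)) seq_len(dim(power$values)[1]) else which(kept)
  sub <- power$values[trials, ch, , tsel, drop = FALSE]
  m <- apply(sub, c(3, 4), mean)
  attr(m, "freqs_hz") <- power$freq_axis
  attr(m, "times_ms") <- power$time_axis[tsel]
  m
}
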