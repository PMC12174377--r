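# Complex Morlet wavelet time-frequency engine.
#
# The decomposition follows the study protocol this package reproduces:
# 87 wavelet frequencies from 4 to 90 Hz in 1 Hz steps, cycle counts
# increasing geometrically from 3 at 4 Hz to 13 at 90 Hz, power sampled on
# interior 20 ms grids only (400-1600 ms within each 2000 ms resting epoch;
# -500..4000 ms for event epochs, with a -2000..-1000 ms dB baseline).

#' Canonical frequency bands
#'
#' Theta 4-7, alpha 8-12, beta 13-30 and gamma 60-90 Hz (inclusive integer
#' bins). The 31-59 Hz range is intentionally not assigned to any band.
#'
#' @return Named list of `c(lo, hi)` Hz pairs.
#' @export
band_spec <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30),
       gamma = c(60, 90))
}

#' Movement periods, analysis grids and baseline window (ms)
#'
#' @return List with `pre_movement` (-500..0), `movement` (0..500),
#'   `post_movement` (1500..4000), `baseline` (-2000..-1000), and the 20 ms
#'   sampling grids `event_grid` (-500..4000) and `resting_grid` (400..1600).
#' @export
period_spec <- function() {
  list(pre_movement = c(-500, 0), movement = c(0, 500),
       post_movement = c(1500, 4000), baseline = c(-2000, -1000),
       event_grid = seq(-500, 4000, by = 20),
       resting_grid = seq(400, 1600, by = 20))
}

#' Build a complex Morlet wavelet bank
#'
#' One Gaussian-windowed complex exponential per frequency, with the cycle
#' count interpolated geometrically between `c_min` at `fmin` and `c_max`
#' at `fmax`: `c_i = c_min * (c_max/c_min)^(i/(n-1))`. The Gaussian SD in
#' time is `cycles / (2 * pi * f)`; kernels extend to +/- 4 SD (odd length)
#' and are unit-energy normalised.
#'
#' @param fmin,fmax,step Frequency grid in Hz (defaults 4, 90, 1).
#' @param c_min,c_max Cycle counts at the grid ends (defaults 3, 13).
#' @param fs Sampling rate of the data to be convolved (default 500).
#' @return Object of class `wavelet_bank`: `freqs_hz`, `cycles`, `sigma_t`
#'   (s), `kernels` (list of complex vectors), `fs`.
#' @export
build_wavelet_bank <- function(fmin = 4, fmax = 90, step = 1,
                               c_min = 3, c_max = 13, fs = 500) {
  stopifnot(fmin <= fmax, c_min <= c_max, step > 0, fs > 0)
  if (fmax >= fs / 2) stop("fmax must be below the Nyquist frequency")
  freqs <- seq(fmin, fmax, by = step)
  n <- length(freqs)
  cycles <- if (n == 1) c_min else {
    cc <- c_min * (c_max / c_min)^((seq_len(n) - 1) / (n - 1))
    cc[1] <- c_min; cc[n] <- c_max  # endpoints exact by construction
    cc
  }
  sigma_t <- cycles / (2 * pi * freqs)
  kernels <- lapply(seq_len(n), function(i) {
    half <- ceiling(4 * sigma_t[i] * fs)
    t <- (-half:half) / fs
    k <- exp(2i * pi * freqs[i] * t) * exp(-t^2 / (2 * sigma_t[i]^2))
    k / sqrt(sum(Mod(k)^2))
  })
  structure(list(freqs_hz = freqs, cycles = cycles, sigma_t = sigma_t,
                 kernels = kernels, fs = fs),
            class = "wavelet_bank")
}

#' Time-frequency power container
#'
#' @param values Numeric array, trials x channels(or ROIs) x freqs x times.
#' @param time_axis Time axis in ms.
#' @param freq_axis Frequencies in Hz.
#' @param channels Channel or ROI labels.
#' @param scale One of `"linear"`, `"db_absolute"`, `"db_baseline"`.
#' @return Object of class `power_tensor`.
#' @export
power_tensor <- function(values, time_axis, freq_axis, channels,
                         scale = c("linear", "db_absolute", "db_baseline")) {
  scale <- match.arg(scale)
  stopifnot(length(dim(values)) == 4L,
            dim(values)[2] == length(channels),
            dim(values)[3] == length(freq_axis),
            dim(values)[4] == length(time_axis))
  if (scale == "linear" && any(values < 0))
    stop("linear-scale power must be non-negative")
  structure(list(values = values, time_axis = time_axis,
                 freq_axis = freq_axis, channels = channels, scale = scale),
            class = "power_tensor")
}

#' @export
print.power_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<power_tensor:%s> %d trials x %d ch x %d freqs x %d times\n",
              x$scale, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Wavelet power of an epoch set on an interior time grid
#'
#' Each epoch is convolved in full with every wavelet (FFT convolution);
#' the squared magnitude of the analytic signal is then sampled only at the
#' requested grid points, which must stay clear of the epoch edges (at
#' least 3 temporal SDs of the longest wavelet), mirroring the
#' interior-window strategy used to avoid edge artifacts.
#'
#' @param epochs An [epoch_set()] (all trials are decomposed; rejection
#'   flags travel with the tensor consumer).
#' @param bank A [build_wavelet_bank()] whose `fs` matches the epochs.
#' @param grid_ms Time grid in ms on the epoch time axis.
#' @return A linear-scale [power_tensor()] (uV^2, up to the unit-energy
#'   wavelet gain).
#' @export
wavelet_power <- function(epochs, bank, grid_ms) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "wavelet_bank"))
  if (abs(epochs$fs - bank$fs) > 1e-9)
    stop("bank and epochs sampling rates differ")
  times <- epochs$epoch_times
  idx <- vapply(grid_ms, function(g) {
    j <- which.min(abs(times - g))
    if (abs(times[j] - g) > 1000 / epochs$fs) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) stop("grid points outside the epoch time axis: ",
                       paste(grid_ms[is.na(idx)], collapse = ", "))
  margin_ms <- 3 * max(bank$sigma_t) * 1000
  lo <- min(times) + margin_ms
  hi <- max(times) - margin_ms
  bad <- grid_ms < lo | grid_ms > hi
  if (any(bad)) stop("grid points inside the edge-artifact zone (",
                     round(lo), "..", round(hi), " ms allowed): ",
                     paste(grid_ms[bad], collapse = ", "))
  d <- dim(epochs$data)
  n_trials <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  max_len <- max(vapply(bank$kernels, length, integer(1)))
  L <- 2^ceiling(log2(n_samp + max_len))
  n_f <- length(bank$freqs_hz)
  kf <- matrix(0 + 0i, nrow = L, ncol = n_f)
  halves <- integer(n_f)
  for (fi in seq_len(n_f)) {
    k <- bank$kernels[[fi]]
    halves[fi] <- (length(k) - 1L) / 2L
    pad <- complex(L)
    pad[seq_along(k)] <- k
    kf[, fi] <- stats::fft(pad)
  }
  out <- array(0, c(n_trials, n_ch, n_f, length(grid_ms)))
  for (ch in seq_len(n_ch)) {
    S <- matrix(0, nrow = L, ncol = n_trials)
    S[seq_len(n_samp), ] <- t(matrix(epochs$data[, ch, ], nrow = n_trials))
    Fs <- stats::mvfft(S)
    for (fi in seq_len(n_f)) {
      conv <- stats::mvfft(Fs * kf[, fi], inverse = TRUE) / L
      rows <- idx + halves[fi]  # full-convolution index of the kernel centre
      p <- Mod(conv[rows, , drop = FALSE])^2
      out[, ch, fi, ] <- t(p)
    }
  }
  power_tensor(out, grid_ms, bank$freqs_hz, epochs$channel_names, "linear")
}

#' Average channels into the two ROI clusters
#'
#' Arithmetic mean of linear power across each cluster's electrodes, per
#' trial, frequency and time point (cluster averaging precedes any dB
#' conversion).
#'
#' @param power Linear-scale [power_tensor()] with electrode channels.
#' @param roi A [roi_spec()].
#' @return A [power_tensor()] with channels `C3` (left) and `C4` (right).
#' @export
roi_average <- function(power, roi = roi_spec()) {
  stopifnot(inherits(power, "power_tensor"))
  if (power$scale != "linear")
    stop("ROI averaging must be done on linear power")
  miss <- setdiff(unlist(roi), power$channels)
  if (length(miss)) stop("missing electrode(s): ", paste(miss, collapse = ", "))
  d <- dim(power$values)
  out <- array(0, c(d[1], 2, d[3], d[4]))
  sides <- list(roi$left, roi$right)
  for (s in 1:2) {
    sel <- match(sides[[s]], power$channels)
    out[, s, , ] <- apply(power$values[, sel, , , drop = FALSE], c(1, 3, 4),
                          mean)
  }
  power_tensor(out, power$time_axis, power$freq_axis, c("C3", "C4"), "linear")
}

#' Convert linear power to absolute dB
#'
#' `10 * log10(power)` (power convention).
#'
#' @param power Linear-scale [power_tensor()] with strictly positive values.
#' @return A `db_absolute` [power_tensor()].
#' @export
to_db <- function(power) {
  stopifnot(inherits(power, "power_tensor"))
  if (power$scale != "linear") stop("to_db expects linear power")
  if (any(power$values <= 0)) stop("nonpositive power cannot be dB-converted")
  power_tensor(10 * log10(power$values), power$time_axis, power$freq_axis,
               power$channels, "db_absolute")
}

# per-trial, per-channel, per-frequency mean power over a baseline window
.baseline_mean <- function(power, baseline_ms) {
  sel <- power$time_axis >= baseline_ms[1] & power$time_axis <= baseline_ms[2]
  if (!any(sel)) stop("baseline window contains no grid points")
  base <- apply(power$values[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  if (any(base <= 0)) stop("zero or negative baseline mean power")
  base
}

#' Baseline-normalise event-related power
#'
#' Per trial, channel and frequency: `10*log10(power / mean baseline
#' power)`, the baseline being the mean linear power over `baseline_ms`
#' (default -2000..-1000 ms) of that same trial/channel/frequency.
#'
#' @param power Linear-scale [power_tensor()] whose grid covers the
#'   baseline window.
#' @param baseline_ms Baseline window in ms.
#' @return A `db_baseline` [power_tensor()].
#' @export
baseline_db <- function(power, baseline_ms = c(-2000, -1000)) {
  stopifnot(inherits(power, "power_tensor"))
  if (power$scale != "linear") stop("baseline_db expects linear power")
  base <- .baseline_mean(power, baseline_ms)
  vals <- 10 * log10(sweep(power$values, c(1, 2, 3), base, "/"))
  power_tensor(vals, power$time_axis, power$freq_axis, power$channels,
               "db_baseline")
}

#' @rdname baseline_db
#' @details [baseline_ratio()] returns the same normalisation on the linear
#'   scale (`power / baseline mean`), the strictly positive response used by
#'   the log-link mixed models and by percent-change maps.
#' @export
baseline_ratio <- function(power, baseline_ms = c(-2000, -1000)) {
  stopifnot(inherits(power, "power_tensor"))
  if (power$scale != "linear") stop("baseline_ratio expects linear power")
  base <- .baseline_mean(power, baseline_ms)
  power_tensor(sweep(power$values, c(1, 2, 3), base, "/"),
               power$time_axis, power$freq_axis, power$channels, "linear")
}

#' Aggregate a power tensor into trial-level band/period records
#'
#' One record per (trial, ROI, band, period): the mean over the band's
#' frequency bins and the period's grid points. Periods are taken as
#' left-closed/right-open intervals except `post_movement`, which includes
#' its upper edge; for resting data a single pseudo-period `"rest"`
#' covering the whole grid is used.
#'
#' @param db_power dB-scale [power_tensor()] (`db_baseline` for event data,
#'   `db_absolute` for resting).
#' @param linear_power Optional linear companion tensor on the same axes
#'   (baseline-ratio for event data, raw linear power for resting); fills
#'   `value_linear`, the response used by the mixed-model stage.
#' @param bands A [band_spec()].
#' @param periods Named list of `c(lo, hi)` ms windows, or `"resting"`.
#' @return Data frame with columns `trial`, `region`, `band`, `period`,
#'   `value_db`, `value_linear`.
#' @export
aggregate_power <- function(db_power, linear_power = NULL,
                            bands = band_spec(), periods = "resting") {
  stopifnot(inherits(db_power, "power_tensor"))
  if (db_power$scale == "linear")
    stop("aggregate_power expects a dB-scale tensor (with optional linear companion)")
  if (!is.null(linear_power)) {
    stopifnot(inherits(linear_power, "power_tensor"),
              identical(dim(linear_power$values), dim(db_power$values)))
  }
  if (identical(periods, "resting")) {
    periods <- list(rest = range(db_power$time_axis))
    closed_right <- "rest"
  } else {
    closed_right <- "post_movement"
  }
  d <- dim(db_power$values)
  rows <- list()
  for (b in names(bands)) {
    fsel <- which(db_power$freq_axis >= bands[[b]][1] &
                    db_power$freq_axis <= bands[[b]][2])
    if (!length(fsel)) stop("band ", b, " has no frequency bins on the axis")
    for (p in names(periods)) {
      w <- periods[[p]]
      tsel <- if (p %in% closed_right) {
        which(db_power$time_axis >= w[1] & db_power$time_axis <= w[2])
      } else {
        which(db_power$time_axis >= w[1] & db_power$time_axis < w[2])
      }
      if (!length(tsel)) stop("period ", p, " has no grid points on the axis")
      for (ch in seq_len(d[2])) {
        sub <- db_power$values[, ch, fsel, tsel, drop = FALSE]
        vdb <- apply(sub, 1, mean)
        vlin <- if (is.null(linear_power)) NA_real_ else {
          apply(linear_power$values[, ch, fsel, tsel, drop = FALSE], 1, mean)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          trial = seq_len(d[1]), region = db_power$channels[ch], band = b,
          period = p, value_db = vdb, value_linear = vlin,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
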