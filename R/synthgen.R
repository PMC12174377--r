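# Synthetic sensorimotor EEG studies with known ground truth.
#
# The generator emulates the recording protocol of a beta-tACS aftereffect
# experiment: 3-min eyes-open resting blocks and self-paced index-finger
# press blocks (60 presses at ~10 s intervals, recorded together with a
# 5 kHz force trace), over the 7-electrode clusters centred at C3 and C4.
# Oscillatory structure is pink noise plus band-limited sinusoids whose
# beta component carries movement-locked ERD/ERS envelopes, so wavelet
# power of every configuration is analytically predictable.

#' Electrode clusters of the two sensorimotor regions of interest
#'
#' Seven electrodes centred at C3 (left M1, under the stimulation site) and
#' the mirrored cluster centred at C4. The first label of each cluster is
#' its centre electrode.
#'
#' @return Named list with character vectors `left` and `right`.
#' @export
roi_spec <- function() {
  list(left  = c("C3", "FC3", "C1", "FC5", "CP1", "C5", "CP3"),
       right = c("C4", "FC4", "C2", "FC6", "CP2", "C6", "CP4"))
}

#' @rdname roi_spec
#' @details `roi_montage()` returns the 14 ROI electrode labels as a flat
#'   vector (the default simulated montage).
#' @export
roi_montage <- function() unlist(roi_spec(), use.names = FALSE)

# within-cluster mixing gains: 1.0 at the centre electrode, 0.8 at neighbours
.roi_gain <- function(labels, roi) ifelse(labels == roi[1], 1.0, 0.8)

# carrier frequencies of the non-beta bands (Hz); beta sits at the
# subject's peak beta frequency
.band_carriers <- c(theta = 6, alpha = 10, gamma = 70)

#' Create a synthetic subject profile
#'
#' Draws the subject-level ground-truth parameters of the generator. The
#' peak beta frequency is uniform on 15-25 Hz by default so that a cohort
#' straddles the 20 Hz stimulation frequency; oscillation amplitudes and the
#' ERD/ERS depths are fixed, physiologically plausible defaults.
#'
#' @param seed Non-negative integer; the draw is deterministic given `seed`.
#' @param overrides Named list overriding any profile field.
#' @return Object of class `subject_profile` with fields `subject_id`,
#'   `peak_beta_hz`, `band_amplitudes` (uV), `noise_exponent`, `noise_sd`
#'   (uV), `erd_depth` (fractional amplitude reduction during the
#'   pre-movement/movement periods), `ers_gain` (fractional amplitude
#'   increase post-movement; power gain is `(1+ers_gain)^2`) and `rng_seed`.
#' @export
make_subject_profile <- function(seed, overrides = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  prof <- with_seed(derive_seed(seed, 0L), {
    list(
      subject_id      = sprintf("sub%05d", as.integer(seed) %% 100000L),
      peak_beta_hz    = stats::runif(1, 15, 25),
      band_amplitudes = c(theta = 1.5, alpha = 2.0, beta = 4.0, gamma = 1.0),
      noise_exponent  = 1.0,
      noise_sd        = 1.5,
      erd_depth       = 0.4,
      ers_gain        = 0.3,
      rng_seed        = as.integer(seed)
    )
  })
  for (nm in names(overrides)) {
    if (!nm %in% names(prof)) stop("unknown profile field: ", nm)
    prof[[nm]] <- overrides[[nm]]
  }
  validate_subject_profile(prof)
  structure(prof, class = "subject_profile")
}

validate_subject_profile <- function(p) {
  if (p$peak_beta_hz < 13 || p$peak_beta_hz > 30)
    stop("peak_beta_hz must lie in [13, 30], got ", p$peak_beta_hz)
  if (p$erd_depth < 0 || p$erd_depth >= 1)
    stop("erd_depth must lie in [0, 1), got ", p$erd_depth)
  if (p$ers_gain < 0) stop("ers_gain must be >= 0")
  if (any(p$band_amplitudes <= 0)) stop("band amplitudes must be > 0")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(p)
}

#' Specify injectable stimulation aftereffects
#'
#' An effect specification carries multiplicative changes of linear band
#' power, keyed by time point, band, region and context (`"resting"` or a
#' movement-period name), plus an additive shift of the subject's peak beta
#' frequency per time point. Sham defaults to all-ones multipliers and zero
#' shift.
#'
#' @param intensity One of `"sham"`, `"0.5"`, `"1.0"`, `"1.5"` (mA).
#' @param rules List of rules built with [effect_rule()].
#' @param peak_shift_hz Named numeric, additive peak-frequency shift per
#'   time point (e.g. `c(post2 = -2)`); unnamed time points shift by 0.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(intensity = "sham", rules = list(),
                        peak_shift_hz = numeric()) {
  intensity <- match.arg(intensity, c("sham", "0.5", "1.0", "1.5"))
  for (r in rules) {
    if (!inherits(r, "effect_rule")) stop("rules must be built by effect_rule()")
  }
  structure(list(intensity = intensity, rules = rules,
                 peak_shift_hz = peak_shift_hz),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @param multiplier Multiplicative change in linear power (> 0).
#' @param time_point,band,region,context Match fields; `NA` is a wildcard.
#'   `context` is `"resting"` or a movement-period name
#'   (`"pre_movement"`, `"movement"`, `"post_movement"`).
#' @export
effect_rule <- function(multiplier, time_point = NA, band = NA,
                        region = NA, context = NA) {
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("effect multiplier must be > 0")
  structure(list(multiplier = multiplier, time_point = time_point,
                 band = band, region = region, context = context),
            class = "effect_rule")
}

#' @rdname effect_spec
#' @param effect An `effect_spec`.
#' @export
effect_multiplier <- function(effect, time_point, band, region, context) {
  m <- 1.0
  for (r in effect$rules) {
    hit <- (is.na(r$time_point) || r$time_point == time_point) &&
      (is.na(r$band)    || r$band == band) &&
      (is.na(r$region)  || r$region == region) &&
      (is.na(r$context) || r$context == context)
    if (hit) m <- m * r$multiplier
  }
  m
}

effect_peak_shift <- function(effect, time_point) {
  s <- effect$peak_shift_hz
  if (time_point %in% names(s)) unname(s[[time_point]]) else 0
}

#' Raw multi-channel recording container
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param fs Sampling rate in Hz.
#' @param channel_names Unique channel labels (10-20 system).
#' @param events Data frame with columns `sample` (1-based, strictly
#'   increasing) and `code`.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channel_names,
                          events = data.frame(sample = integer(),
                                              code = character())) {
  stopifnot(is.matrix(data), fs > 0, nrow(data) == length(channel_names))
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (nrow(events)) {
    if (is.unsorted(events$sample, strictly = TRUE))
      stop("event samples must be strictly increasing")
    if (any(events$sample < 1 | events$sample > ncol(data)))
      stop("event sample out of range")
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

# 1/f^x background noise; the spectrum is flattened below 0.5 Hz (mirroring
# the acquisition high-pass) so the variance stays finite.
pink_noise <- function(n, fs, exponent = 1, sd_target = 1) {
  if (sd_target == 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- seq(0, fs - fs / n, length.out = n)
  f[f > fs / 2] <- fs - f[f > fs / 2]   # fold to physical frequency
  f <- pmax(f, 0.5)
  h <- 1 / f^(exponent / 2)
  x <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_target / stats::sd(x)
}

# Piecewise envelope: flat segments (t0, t1, level) joined by raised-cosine
# ramps across the gaps; constant at the outer levels beyond the ends.
piecewise_envelope <- function(t, flats) {
  lev <- numeric(length(t)) + flats[[1]]$level
  for (i in seq_along(flats)) {
    f <- flats[[i]]
    lev[t >= f$t0 & t <= f$t1] <- f$level
    if (i < length(flats)) {
      g0 <- f$t1; g1 <- flats[[i + 1]]$t0
      if (g1 > g0) {
        in_gap <- t > g0 & t < g1
        u <- (t[in_gap] - g0) / (g1 - g0)
        lev[in_gap] <- f$level +
          (flats[[i + 1]]$level - f$level) * (1 - cos(pi * u)) / 2
      }
    }
  }
  lev[t > flats[[length(flats)]]$t1] <- flats[[length(flats)]]$level
  lev
}

.check_channels <- function(channels) {
  known <- roi_montage()
  bad <- setdiff(channels, known)
  if (length(bad)) stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(known, channels)
  if (length(miss)) stop("channels must include all 14 ROI electrodes; missing: ",
                         paste(miss, collapse = ", "))
  invisible(channels)
}

# Oscillatory source for one ROI: sum of band sinusoids with given
# amplitude envelopes (constant or movement-locked), random phase per call.
.roi_source <- function(tt, profile, amp_scale, beta_hz, envelopes = NULL) {
  src <- numeric(length(tt))
  bands <- names(profile$band_amplitudes)
  for (b in bands) {
    f <- if (b == "beta") beta_hz else .band_carriers[[b]]
    a <- profile$band_amplitudes[[b]] * amp_scale[[b]]
    env <- if (is.null(envelopes[[b]])) 1 else envelopes[[b]]
    src <- src + a * env * cos(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  }
  src
}

#' Simulate one resting-state block
#'
#' Pink-noise background plus theta/alpha/beta/gamma sinusoids mixed into
#' the two ROI clusters; the beta component sits at the subject's peak beta
#' frequency (plus any injected shift), and each band/ROI amplitude is
#' scaled by the square root of the effect's linear-power multiplier for
#' the given time point.
#'
#' @param profile A [make_subject_profile()] object.
#' @param duration_s Block duration in seconds (default 180, i.e. 3 min).
#' @param fs Sampling rate in Hz (default 1000).
#' @param channels Channel labels; must include the 14 ROI electrodes.
#' @param effect An [effect_spec()].
#' @param time_point Time-point label (`"pre"`, `"post1"`, `"post2"`).
#' @return A [raw_recording()].
#' @export
simulate_resting_block <- function(profile, duration_s = 180, fs = 1000,
                                   channels = roi_montage(),
                                   effect = effect_spec("sham"),
                                   time_point = "pre") {
  stopifnot(duration_s > 0, fs > 0)
  .check_channels(channels)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  beta_hz <- profile$peak_beta_hz + effect_peak_shift(effect, time_point)
  rois <- roi_spec()
  roi_names <- c(left = "C3", right = "C4")
  sources <- list()
  for (side in c("left", "right")) {
    amp_scale <- vapply(names(profile$band_amplitudes), function(b) {
      sqrt(effect_multiplier(effect, time_point, b, roi_names[[side]],
                             "resting"))
    }, numeric(1))
    sources[[side]] <- .roi_source(tt, profile, amp_scale, beta_hz)
  }
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  for (side in c("left", "right")) {
    labs <- intersect(rois[[side]], channels)
    g <- .roi_gain(labs, rois[[side]])
    for (k in seq_along(labs)) {
      data[labs[k], ] <- g[k] * sources[[side]]
    }
  }
  for (ch in seq_along(channels)) {
    data[ch, ] <- data[ch, ] +
      pink_noise(n, fs, profile$noise_exponent, profile$noise_sd)
  }
  raw_recording(data, fs, channels)
}

# movement-locked amplitude envelope flats for one trial, times in seconds
# relative to press onset; levels already include sqrt(power multiplier)
.trial_flats <- function(lev_pre, lev_mov, lev_post) {
  list(list(t0 = -Inf, t1 = -0.7, level = 1),
       list(t0 = -0.5, t1 = 0.0,  level = lev_pre),
       list(t0 = 0.0,  t1 = 0.5,  level = lev_mov),
       list(t0 = 1.5,  t1 = 4.0,  level = lev_post),
       list(t0 = 4.3,  t1 = Inf,  level = 1))
}

#' Simulate one self-paced movement block with its force trace
#'
#' Sixty (by default) self-paced presses at jittered ~10 s intervals. The
#' beta-band amplitude follows a movement-locked envelope around each press
#' onset: pre-movement ERD (-500 to 0 ms) and movement ERD (0-500 ms) at
#' `1 - erd_depth`, post-movement ERS (1500-4000 ms) at `1 + ers_gain`,
#' joined by raised-cosine ramps, each level further scaled by the square
#' root of the effect's per-period power multiplier. The force trace holds a
#' Gaussian press pulse (peak 2 N, sigma 80 ms) per onset; the recorded
#' ground-truth onset is the first sample above the force threshold.
#'
#' @inheritParams simulate_resting_block
#' @param n_trials Number of presses (default 60, performed as two blocks
#'   of 30 in the emulated protocol).
#' @param iti_s Mean inter-press interval in seconds (default 10).
#' @param iti_jitter_s Half-width of the uniform jitter (default 1).
#' @param force_fs Force-trace sampling rate in Hz (default 5000).
#' @param force_threshold_n Press-onset threshold in newtons (default 0.5).
#' @return List with elements `raw` (a [raw_recording()] whose events mark
#'   the press onsets at the EEG rate) and `force` (class `force_trace`:
#'   `samples` in N, `fs`, and ground-truth `true_onsets` at the force rate).
#' @export
simulate_movement_block <- function(profile, n_trials = 60, iti_s = 10,
                                    fs = 1000, channels = roi_montage(),
                                    effect = effect_spec("sham"),
                                    time_point = "pre",
                                    iti_jitter_s = 1, force_fs = 5000,
                                    force_threshold_n = 0.5) {
  stopifnot(n_trials >= 1, fs > 0)
  .check_channels(channels)
  epoch_span <- 7.0  # -2.5 .. 4.5 s
  if (iti_s - iti_jitter_s < epoch_span)
    stop("inter-trial interval too short for the -2500..4500 ms epoch window")
  itis <- stats::runif(max(n_trials - 1, 0), iti_s - iti_jitter_s,
                       iti_s + iti_jitter_s)
  lead_in <- 5
  onsets_s <- lead_in + c(0, cumsum(itis))
  duration_s <- ceiling(onsets_s[n_trials] + 5.5)
  n <- duration_s * fs
  tt <- (seq_len(n) - 1) / fs
  beta_hz <- profile$peak_beta_hz + effect_peak_shift(effect, time_point)
  rois <- roi_spec()
  roi_names <- c(left = "C3", right = "C4")
  periods <- c("pre_movement", "movement", "post_movement")

  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  # trial segments: midpoints between consecutive onsets, so each trial's
  # oscillation gets an independent phase
  bounds <- c(0, (onsets_s[-1] + onsets_s[-n_trials]) / 2, duration_s)[
    seq_len(n_trials + 1)]
  if (n_trials == 1) bounds <- c(0, duration_s)

  for (side in c("left", "right")) {
    region <- roi_names[[side]]
    mult <- sapply(periods, function(p) {
      vapply(names(profile$band_amplitudes), function(b) {
        effect_multiplier(effect, time_point, b, region, p)
      }, numeric(1))
    })  # bands x periods
    src <- numeric(n)
    for (k in seq_len(n_trials)) {
      seg <- tt >= bounds[k] & tt < bounds[k + 1]
      trel <- tt[seg] - onsets_s[k]
      envs <- list()
      for (b in names(profile$band_amplitudes)) {
        erd <- if (b == "beta") profile$erd_depth else 0
        ers <- if (b == "beta") profile$ers_gain else 0
        flats <- .trial_flats((1 - erd) * sqrt(mult[b, 1]),
                              (1 - erd) * sqrt(mult[b, 2]),
                              (1 + ers) * sqrt(mult[b, 3]))
        envs[[b]] <- piecewise_envelope(trel, flats)
      }
      amp_scale <- c(theta = 1, alpha = 1, beta = 1, gamma = 1)
      src[seg] <- .roi_source(tt[seg], profile, amp_scale, beta_hz, envs)
    }
    labs <- intersect(rois[[side]], channels)
    g <- .roi_gain(labs, rois[[side]])
    for (k in seq_along(labs)) data[labs[k], ] <- g[k] * src
  }
  for (ch in seq_along(channels)) {
    data[ch, ] <- data[ch, ] +
      pink_noise(n, fs, profile$noise_exponent, profile$noise_sd)
  }

  # force trace: Gaussian pulse whose threshold crossing sits exactly at the
  # press onset; small sub-threshold sensor noise
  nf <- duration_s * force_fs
  tf <- (seq_len(nf) - 1) / force_fs
  sigma <- 0.08; peak <- 2.0
  lead <- sigma * sqrt(2 * log(peak / force_threshold_n))
  force <- stats::rnorm(nf, 0, 0.005)
  for (k in seq_len(n_trials)) {
    t_pk <- onsets_s[k] + lead
    win <- which(tf > t_pk - 4 * sigma & tf < t_pk + 4 * sigma)
    force[win] <- force[win] + peak * exp(-(tf[win] - t_pk)^2 / (2 * sigma^2))
  }
  true_onsets <- round(onsets_s * force_fs) + 1L
  events <- data.frame(sample = round(onsets_s * fs) + 1L, code = "press",
                       stringsAsFactors = FALSE)
  list(raw = raw_recording(data, fs, channels, events),
       force = structure(list(samples = force, fs = force_fs,
                              true_onsets = true_onsets),
                         class = "force_trace"))
}

#' Generate a full synthetic study on disk
#'
#' Writes one resting and one movement recording (EDF) per subject,
#' stimulation intensity and time point, together with press-event and
#' force-trace CSV sidecars and a machine-readable ground-truth JSON of all
#' injected effects. The layout is
#' `out_dir/<subject>/<intensity>/<time_point>/{rest,task}.edf`.
#'
#' @param config Study configuration list (see [default_config()]); the
#'   fields used here are `n_subjects`, `intensities`, `time_points`,
#'   `effects` (named list of [effect_spec()] by intensity), `duration_rest_s`,
#'   `n_trials`, `iti_s`, `fs`, `force_fs`, `out_dir`.
#' @param seed Master seed; every block draws from a derived substream, so
#'   the study is bit-reproducible.
#' @return Invisibly, a list with the subject profiles, file index and the
#'   ground-truth path.
#' @export
generate_study <- function(config, seed) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  profiles <- lapply(seq_len(cfg$n_subjects), function(i) {
    make_subject_profile(derive_seed(seed, 100000L + i),
                         overrides = list(subject_id = subjects[i]))
  })
  names(profiles) <- subjects
  files <- list()
  counter <- 0L
  for (i in seq_len(cfg$n_subjects)) {
    for (intensity in cfg$intensities) {
      eff <- as_effect_spec(cfg$effects[[intensity]], intensity)
      for (tp in cfg$time_points) {
        d <- file.path(cfg$out_dir, subjects[i], intensity, tp)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        counter <- counter + 1L
        rest <- with_seed(derive_seed(seed, counter), {
          simulate_resting_block(profiles[[i]], cfg$duration_rest_s, cfg$fs,
                                 cfg$channels, eff, tp)
        })
        write_edf(rest, file.path(d, "rest.edf"))
        counter <- counter + 1L
        task <- with_seed(derive_seed(seed, counter), {
          simulate_movement_block(profiles[[i]], cfg$n_trials, cfg$iti_s,
                                  cfg$fs, cfg$channels, eff, tp,
                                  force_fs = cfg$force_fs,
                                  force_threshold_n = cfg$force_threshold_n)
        })
        write_edf(task$raw, file.path(d, "task.edf"))
        utils::write.csv(task$raw$events, file.path(d, "task_events.csv"),
                         row.names = FALSE)
        utils::write.csv(
          data.frame(sample = seq_along(task$force$samples),
                     newtons = round(task$force$samples, 5)),
          file.path(d, "task_force.csv"), row.names = FALSE)
        utils::write.csv(data.frame(sample = task$force$true_onsets),
                         file.path(d, "task_true_onsets.csv"),
                         row.names = FALSE)
        files[[paste(subjects[i], intensity, tp, sep = "/")]] <- d
      }
    }
  }
  gt <- list(
    seed = seed,
    n_subjects = cfg$n_subjects,
    intensities = cfg$intensities,
    time_points = cfg$time_points,
    profiles = lapply(profiles, function(p) p[c(
      "subject_id", "peak_beta_hz", "band_amplitudes", "noise_exponent",
      "noise_sd", "erd_depth", "ers_gain")]),
    effects = lapply(cfg$intensities, function(intensity) {
      eff <- as_effect_spec(cfg$effects[[intensity]], intensity)
      list(intensity = intensity,
           rules = lapply(eff$rules, unclass),
           peak_shift_hz = as.list(eff$peak_shift_hz))
    })
  )
  gt_path <- file.path(cfg$out_dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(profiles = profiles, files = files,
                 ground_truth = gt_path))
}
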