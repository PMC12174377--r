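test_that("subject profiles are deterministic, overridable and validated", {
  p1 <- make_subject_profile(1)
  p2 <- make_subject_profile(1)
  expect_identical(p1, p2)
  p3 <- make_subject_profile(1, overrides = list(peak_beta_hz = 17))
  expect_equal(p3$peak_beta_hz, 17)
  expect_error(make_subject_profile(1, overrides = list(peak_beta_hz = 40)),
               "peak_beta_hz")
  expect_error(make_subject_profile(1, overrides = list(erd_depth = 1)),
               "erd_depth")
  expect_error(make_subject_profile(1, overrides = list(nonsense = 1)),
               "unknown profile field")
})

test_that("peak beta sampler stays within its documented bounds", {
  peaks <- vapply(seq_len(1000), function(s) {
    make_subject_profile(s)$peak_beta_hz
  }, numeric(1))
  expect_true(all(peaks >= 15 & peaks <= 25))
  # the cohort straddles the 20 Hz stimulation frequency
  expect_gt(sum(peaks > 20), 100)
  expect_gt(sum(peaks < 20), 100)
})

test_that("effect rules compose and sham is the identity", {
  sham <- effect_spec("sham")
  expect_equal(effect_multiplier(sham, "post1", "beta", "C3", "resting"), 1)
  expect_equal(effect_peak_shift(sham, "post2"), 0)
  eff <- effect_spec("1.0",
                     list(effect_rule(2, band = "beta", region = "C3"),
                          effect_rule(1.5, time_point = "post2")),
                     peak_shift_hz = c(post2 = -2))
  expect_equal(effect_multiplier(eff, "post2", "beta", "C3", "resting"), 3)
  expect_equal(effect_multiplier(eff, "pre", "beta", "C3", "movement"), 2)
  expect_equal(effect_multiplier(eff, "post1", "alpha", "C4", "resting"), 1)
  expect_equal(effect_peak_shift(eff, "post2"), -2)
  expect_error(effect_rule(0), "> 0")
})

test_that("resting blocks have the right geometry and channel checks", {
  p <- make_subject_profile(2)
  set.seed(1)
  r <- simulate_resting_block(p, duration_s = 10)
  expect_s3_class(r, "raw_recording")
  expect_equal(ncol(r$data), 10 * 1000)
  expect_equal(nrow(r$data), 14)
  expect_error(simulate_resting_block(p, channels = c("C3", "Oz")),
               "unknown channel")
  expect_error(simulate_resting_block(p, channels = roi_spec()$left),
               "missing")
})

test_that("a resting block's spectrum peaks at the profile's beta frequency", {
  p <- make_subject_profile(3, overrides = list(peak_beta_hz = 17))
  set.seed(5)
  r <- simulate_resting_block(p, duration_s = 30)
  # independent oracle: raw FFT periodogram of the centre electrode
  x <- r$data["C3", ]
  pg <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) * r$fs / length(x)
  sel <- fr >= 13 & fr <= 30
  expect_lt(abs(fr[sel][which.max(pg[sel])] - 17), 1)
})

test_that("movement blocks produce the requested presses with epochable spacing", {
  p <- make_subject_profile(4)
  set.seed(2)
  mv <- simulate_movement_block(p, n_trials = 60)
  expect_length(mv$force$true_onsets, 60)
  expect_equal(nrow(mv$raw$events), 60)
  # every onset admits a full -2500..4500 ms epoch without overlap
  on_s <- (mv$force$true_onsets - 1) / mv$force$fs
  expect_true(all(diff(on_s) >= 7))
  expect_gt(on_s[1], 2.5)
  expect_lt(on_s[60] + 4.5, ncol(mv$raw$data) / mv$raw$fs)
  # force pulses peak near 2 N
  expect_equal(max(mv$force$samples), 2, tolerance = 0.02)
  expect_error(simulate_movement_block(p, n_trials = 2, iti_s = 5),
               "too short")
})

test_that("a null ERD/ERS profile leaves baselined beta power flat", {
  p <- make_subject_profile(5, overrides = list(erd_depth = 0, ers_gain = 0,
                                                peak_beta_hz = 20))
  set.seed(6)
  mv <- simulate_movement_block(p, n_trials = 6)
  rc <- condition_raw(mv$raw)
  ep <- suppressWarnings(
    reject_epochs(make_epochs(rc, "event", detect_movement_onsets(mv$force))))
  ps <- period_spec()
  grid <- sort(unique(c(seq(-2000, -1000, 20), ps$event_grid)))
  db <- baseline_db(roi_average(wavelet_power(ep, build_wavelet_bank(), grid)))
  m <- apply(db$values[, 1, db$freq_axis == 20, ], 2, mean)
  for (w in list(c(-500, 0), c(0, 500), c(1500, 4000))) {
    sel <- db$time_axis >= w[1] & db$time_axis <= w[2]
    expect_lt(abs(mean(m[sel])), 0.5)
  }
})

test_that("generated studies are reproducible and follow the layout", {
  cfg <- list(n_subjects = 2, intensities = c("sham", "1.0"),
              time_points = c("pre", "post2"), duration_rest_s = 4,
              n_trials = 1, out_dir = file.path(tempdir(), "studyA"))
  g1 <- generate_study(cfg, seed = 11)
  # 2 subjects x 2 intensities x 2 time points x 2 recording types
  edfs <- list.files(cfg$out_dir, pattern = "\\.edf$", recursive = TRUE)
  expect_length(edfs, 2 * 2 * 2 * 2)
  expect_true(file.exists(file.path(cfg$out_dir, "sub01", "1.0", "post2",
                                    "task.edf")))
  cfg2 <- cfg
  cfg2$out_dir <- file.path(tempdir(), "studyB")
  generate_study(cfg2, seed = 11)
  expect_identical(readLines(file.path(cfg$out_dir, "ground_truth.json")),
                   readLines(file.path(cfg2$out_dir, "ground_truth.json")))
  expect_identical(unname(tools::md5sum(file.path(cfg$out_dir, "sub01",
                                                  "1.0", "pre", "rest.edf"))),
                   unname(tools::md5sum(file.path(cfg2$out_dir, "sub01",
                                                  "1.0", "pre", "rest.edf"))))
  unlink(c(cfg$out_dir, cfg2$out_dir), recursive = TRUE)
})

test_that("EDF files round-trip within quantization error", {
  p <- make_subject_profile(6)
  set.seed(9)
  r <- simulate_resting_block(p, duration_s = 3)
  path <- tempfile(fileext = ".edf")
  write_edf(r, path)
  r2 <- read_edf(path)
  expect_equal(r2$fs, r$fs)
  expect_identical(r2$channel_names, r$channel_names)
  quant <- max(abs(r$data)) * 1.01 / 32767
  expect_lt(max(abs(r$data - r2$data[, seq_len(ncol(r$data))])), 2 * quant)
  # non-integer duration is zero-padded to whole seconds
  r3 <- raw_recording(matrix(sin(1:1500 / 20), 1), 1000, "C3")
  write_edf(r3, path)
  r4 <- read_edf(path)
  expect_equal(ncol(r4$data), 2000)
  expect_lt(max(abs(r4$data[1, 1:1500] - r3$data[1, ])), 1e-3)
  unlink(path)
})
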