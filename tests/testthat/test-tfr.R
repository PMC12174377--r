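test_that("the wavelet bank matches the printed protocol", {
  b <- build_wavelet_bank()
  expect_length(b$kernels, 87)
  expect_identical(b$cycles[1], 3)
  expect_identical(b$cycles[87], 13)
  # geometric schedule: midpoint of 0..86 is sqrt(3 * 13)
  expect_equal(b$cycles[44], sqrt(39), tolerance = 1e-12)
  expect_true(all(diff(b$freqs_hz) == 1))
  expect_true(all(diff(b$cycles) > 0))
  lens <- vapply(b$kernels, length, integer(1))
  expect_true(all(lens %% 2 == 1))
  expect_true(all(lens >= 2 * 4 * b$sigma_t * b$fs))
  # unit energy
  en <- vapply(b$kernels, function(k) sum(Mod(k)^2), numeric(1))
  expect_equal(en, rep(1, 87), tolerance = 1e-12)
  # degenerate single-frequency bank
  b1 <- build_wavelet_bank(4, 4, 1, 3, 13, 500)
  expect_length(b1$kernels, 1)
  expect_identical(b1$cycles, 3)
  expect_error(build_wavelet_bank(fmax = 300, fs = 500), "Nyquist")
})

test_that("kernel temporal SD follows cycles / (2 pi f)", {
  b <- build_wavelet_bank()
  for (i in c(1, 30, 87)) {
    k <- b$kernels[[i]]
    t <- (seq_along(k) - (length(k) + 1) / 2) / b$fs
    w <- Mod(k)  # Gaussian envelope
    sd_meas <- sqrt(sum(w * t^2) / sum(w))
    expect_equal(sd_meas, b$sigma_t[i], tolerance = 0.02)
  }
  # temporal SD follows cycles / (2 pi f) exactly
  expect_equal(b$sigma_t, b$cycles / (2 * pi * b$freqs_hz), tolerance = 1e-12)
})

make_epoch_from <- function(x, fs = 500, t0_ms = 0) {
  epoch_set(array(x, c(1, 1, length(x))),
            t0_ms + (seq_along(x) - 1) / fs * 1000, fs, "resting", "C3")
}

test_that("wavelet power localises tones and scales quadratically", {
  fs <- 500
  tt <- (0:(2 * fs - 1)) / fs
  bank <- build_wavelet_bank(fs = fs)
  grid <- seq(400, 1600, 20)
  ep <- make_epoch_from(sin(2 * pi * 10 * tt))
  pw <- wavelet_power(ep, bank, grid)
  peaks <- apply(pw$values[1, 1, , ], 2, which.max)
  expect_true(all(pw$freq_axis[peaks] == 10))
  ep2 <- make_epoch_from(2 * sin(2 * pi * 10 * tt))
  pw2 <- wavelet_power(ep2, bank, grid)
  expect_equal(pw2$values[1, 1, pw$freq_axis == 10, ],
               4 * pw$values[1, 1, pw$freq_axis == 10, ], tolerance = 1e-9)
  # grid points in the edge-artifact zone are refused
  expect_error(wavelet_power(ep, bank, seq(0, 1600, 20)), "edge-artifact")
})

test_that("pink-noise wavelet spectra match an FFT-based oracle", {
  fs <- 500
  set.seed(21)
  n_tr <- 40
  x <- replicate(n_tr, tacsbeta:::pink_noise(2 * fs, fs, 1, 1))
  dat <- array(0, c(n_tr, 1, 2 * fs))
  for (i in seq_len(n_tr)) dat[i, 1, ] <- x[, i]
  ep <- epoch_set(dat, (0:(2 * fs - 1)) / fs * 1000, fs, "resting", "C3")
  bank <- build_wavelet_bank(fs = fs)
  pw <- wavelet_power(ep, bank, seq(400, 1600, 20))
  wav_spec <- apply(pw$values[, 1, , ], 2, mean)
  # oracle: periodogram averaged across trials, smoothed with each
  # wavelet's Gaussian frequency response
  pg <- rowMeans(Mod(stats::mvfft(x))^2)
  fr <- (seq_len(2 * fs) - 1) * fs / (2 * fs)
  oracle <- vapply(seq_along(bank$freqs_hz), function(i) {
    sf <- 1 / (2 * pi * bank$sigma_t[i])
    w <- exp(-(fr - bank$freqs_hz[i])^2 / (2 * sf^2))
    sum(w * pg) / sum(w)
  }, numeric(1))
  # compare normalised spectral shapes
  a <- wav_spec / mean(wav_spec)
  b <- oracle / mean(oracle)
  expect_lt(max(abs(a - b) / b), 0.15)
})

test_that("ROI averaging equals the element-wise mean oracle", {
  chans <- roi_montage()
  set.seed(22)
  vals <- array(abs(rnorm(3 * 14 * 4 * 5)), c(3, 14, 4, 5))
  pw <- power_tensor(vals, seq(0, 80, 20), 1:4, chans, "linear")
  ra <- roi_average(pw)
  roi <- roi_spec()
  for (s in 1:2) {
    sel <- match(list(roi$left, roi$right)[[s]], chans)
    brute <- apply(vals[, sel, , , drop = FALSE], c(1, 3, 4), mean)
    expect_equal(ra$values[, s, , ], brute, tolerance = 1e-12)
  }
  # identical electrodes -> ROI equals any one of them
  vals2 <- vals
  for (k in seq_along(chans)) vals2[, k, , ] <- vals[, 1, , ]
  ra2 <- roi_average(power_tensor(vals2, seq(0, 80, 20), 1:4, chans, "linear"))
  expect_equal(ra2$values[, 1, , ], vals[, 1, , ], tolerance = 1e-12)
  # one electrode at 2, six at 0 -> 2/7
  vals3 <- array(0, c(1, 14, 1, 1))
  vals3[1, 1, 1, 1] <- 2
  ra3 <- roi_average(power_tensor(vals3, 0, 1, chans, "linear"))
  expect_equal(ra3$values[1, 1, 1, 1], 2 / 7)
  expect_error(roi_average(power_tensor(vals3[, 1:3, , , drop = FALSE], 0, 1,
                                        chans[1:3], "linear")),
               "missing electrode")
})

test_that("dB conversion and baselining follow the closed forms", {
  v <- array(c(1, 10, 0.5, 2), c(1, 1, 1, 4))
  pw <- power_tensor(v, seq(0, 60, 20), 20, "C3", "linear")
  db <- to_db(pw)
  expect_equal(as.numeric(db$values), c(0, 10, 10 * log10(0.5), 10 * log10(2)))
  expect_error(to_db(power_tensor(array(0, c(1, 1, 1, 1)), 0, 1, "C3",
                                  "linear")), "nonpositive")
  # dB transforms preserve order
  expect_identical(order(v), order(db$values))
  # stationary epoch baselines to ~0 dB; doubled power -> +3.01 dB
  set.seed(23)
  vals <- array(abs(rnorm(24, 10, 0.01)), c(2, 1, 2, 6))
  times <- c(-2000, -1500, -1000, 0, 20, 40)
  st <- power_tensor(vals, times, c(10, 20), "C3", "linear")
  bdb <- baseline_db(st, c(-2000, -1000))
  expect_lt(max(abs(apply(bdb$values, c(1, 2, 3), mean))), 0.5)
  vals2 <- vals
  vals2[, , , 4:6] <- vals2[, , , 4:6] * 2
  b2 <- baseline_db(power_tensor(vals2, times, c(10, 20), "C3", "linear"))
  expect_equal(mean(b2$values[, , , 4:6]), 10 * log10(2), tolerance = 0.01)
  # 50% amplitude -> -6.02 dB
  vals3 <- vals
  vals3[, , , 4:6] <- vals3[, , , 4:6] * 0.25
  b3 <- baseline_db(power_tensor(vals3, times, c(10, 20), "C3", "linear"))
  expect_equal(mean(b3$values[, , , 4:6]), 10 * log10(0.25), tolerance = 0.01)
  # linear companion: baseline_ratio is the linear analogue
  r2 <- baseline_ratio(power_tensor(vals2, times, c(10, 20), "C3", "linear"))
  expect_equal(10 * log10(r2$values), b2$values, tolerance = 1e-9)
})

test_that("aggregation equals a nested-loop oracle and is linear", {
  set.seed(24)
  freqs <- 4:90
  times <- seq(-500, 4000, 20)
  vals <- array(rnorm(2 * 2 * 87 * 226), c(2, 2, 87, 226))
  db <- power_tensor(vals, times, freqs, c("C3", "C4"), "db_baseline")
  lin <- power_tensor(abs(vals) + 1, times, freqs, c("C3", "C4"), "linear")
  ps <- period_spec()
  periods <- ps[c("pre_movement", "movement", "post_movement")]
  agg <- aggregate_power(db, lin, periods = periods)
  bands <- band_spec()
  # beta spans 18 integer bins
  expect_equal(sum(freqs >= 13 & freqs <= 30), 18)
  for (row in sample(nrow(agg), 20)) {
    r <- agg[row, ]
    fsel <- which(freqs >= bands[[r$band]][1] & freqs <= bands[[r$band]][2])
    w <- periods[[r$period]]
    tsel <- if (r$period == "post_movement") {
      which(times >= w[1] & times <= w[2])
    } else which(times >= w[1] & times < w[2])
    ch <- match(r$region, c("C3", "C4"))
    acc <- 0; nacc <- 0
    for (f in fsel) for (t in tsel) {
      acc <- acc + vals[r$trial, ch, f, t]
      nacc <- nacc + 1
    }
    expect_equal(r$value_db, acc / nacc, tolerance = 1e-9)
  }
  # uniform tensor -> every record equals the constant
  u <- power_tensor(array(2.5, c(1, 2, 87, 226)), times, freqs,
                    c("C3", "C4"), "db_baseline")
  aggu <- aggregate_power(u, periods = periods)
  expect_true(all(abs(aggu$value_db - 2.5) < 1e-12))
  # linearity on the linear companion
  lin2 <- lin
  lin2$values <- 3 * lin2$values
  agg2 <- aggregate_power(db, lin2, periods = periods)
  expect_equal(agg2$value_linear, 3 * agg$value_linear, tolerance = 1e-12)
})

test_that("the synthetic ERD/ERS sign pattern matches sensorimotor physiology", {
  fx <- movement_fixture()
  db <- fx$db
  f17 <- db$freq_axis == 17
  for (ch in 1:2) {
    m <- apply(db$values[, ch, f17, ], 2, mean)
    pre <- mean(m[db$time_axis >= -500 & db$time_axis < 0])
    mov <- mean(m[db$time_axis >= 0 & db$time_axis < 500])
    post <- mean(m[db$time_axis >= 1500 & db$time_axis <= 4000])
    expect_lt(pre, 0)
    expect_lt(mov, 0)
    expect_gt(post, 0)
  }
})
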