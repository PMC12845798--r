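test_that("bandpass suppresses DC, preserves the passband, attenuates above it", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  # DC is below the 0.3 Hz edge (trim the slow 0.3 Hz edge transients)
  y <- bandpass(rep(2, length(t)), fs, 0.3, 24)
  core <- y[(10 * fs):(20 * fs)]
  expect_lt(max(abs(core)), 1e-3)
  # 5 Hz tone passes within 5% (oracle: FFT amplitude)
  amp_at <- function(x, f0) {
    n <- length(x)
    a <- abs(fft(x)) / n * 2
    fr <- (0:(n - 1)) * fs / n
    max(a[abs(fr - f0) < 0.05])
  }
  y5 <- bandpass(sin(2 * pi * 5 * t), fs, 0.3, 24)
  expect_equal(amp_at(y5, 5), 1, tolerance = 0.05)
  # 40 Hz tone attenuated by at least 20 dB
  y40 <- bandpass(sin(2 * pi * 40 * t), fs, 0.3, 24)
  expect_lt(20 * log10(amp_at(y40, 40)), -20)
  expect_error(bandpass(t, fs, 0.3, 60), "Nyquist|lo < hi")
})

test_that("resampling keeps length arithmetic and spectral content", {
  x <- rnorm(10000)
  expect_length(resample_to_target(x, 1000, 100), 1000)
  expect_identical(resample_to_target(x, 100, 100), x)
  expect_error(resample_to_target(x, 50, 100), "upsampling")
  t <- seq(0, 10, by = 1 / 1000)
  y <- resample_to_target(sin(2 * pi * 2 * t), 1000, 100)
  a <- abs(fft(y))
  fr <- (0:(length(y) - 1)) * 100 / length(y)
  expect_equal(fr[which.max(a[1:(length(y) / 2)])], 2, tolerance = 0.05)
})

test_that("missing samples are linearly imputed with edge fill", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(NA, 5, 5)), c(5, 5, 5))
  y <- 0.5 * (0:199)
  miss <- y
  set.seed(4)
  miss[sample(2:199, 10)] <- NA
  expect_equal(interpolate_missing(miss), y)
  expect_error(interpolate_missing(c(NA, NA)), "all-missing")
})

test_that("R-peak detection finds clean beats and honours the refractory rule", {
  expect_identical(detect_r_peaks(numeric(1000), 100), integer(0))
  bp <- generate_beat_times(10, 60, hrv_sd = 0, seed = 1)
  rec <- synthesize_record(bp, fs = 100, noise = noise_off())
  idx <- detect_r_peaks(rec$ecg, 100)
  expect_gte(length(idx), 9)
  for (i in idx) {
    expect_lte(min(abs((i - 1) / 100 - bp$beat_times)), 0.010)
  }
  expect_true(all(diff(idx) >= 0.25 * 100))
  # two candidate spikes 100 ms apart: only the larger survives
  t <- (0:999) / 100
  spike <- function(t0, a) a * exp(-((t - t0) / 0.010)^2)
  ecg <- spike(3, 1) + spike(3.1, 0.6) + spike(5, 1) + spike(7, 1)
  idx <- detect_r_peaks(ecg, 100)
  expect_true(any(abs(idx - 301) <= 1))
  expect_false(any(abs(idx - 311) <= 1))
})

test_that("window heart rate is 60 over the mean RR", {
  expect_equal(hr_from_window(c(0, 0.8, 1.6, 2.4, 3.2)), 75)
  expect_equal(hr_from_window(c(0, 1, 2, 3)), 60)
  expect_equal(hr_from_window(cumsum(c(0, 0.7, 0.8, 0.9))), 75)
  expect_true(is.na(hr_from_window(1.5)))
})

test_that("window counts follow the sliding-window formula", {
  cfg <- preprocess_config()
  mk_rec <- function(dur) {
    bp <- generate_beat_times(dur, 72, hrv_sd = 0, seed = 1)
    synthesize_record(bp, fs = 100, noise = noise_off(), duration_s = dur)
  }
  expect_equal(nrow(segment_windows(mk_rec(10), cfg)), 7)
  expect_equal(segment_windows(mk_rec(10), cfg)$t_start, 0:6)
  expect_equal(nrow(segment_windows(mk_rec(4), cfg)), 1)
  expect_equal(nrow(segment_windows(mk_rec(3.9), cfg)), 0)
  # property: random record lengths
  set.seed(11)
  for (dur in runif(6, 4, 40)) {
    n <- round(dur * 100)
    expected <- floor((n / 100 - 4) / 1) + 1
    expect_equal(nrow(segment_windows(mk_rec(dur), cfg)), expected)
  }
})

test_that("labels match ground truth on clean records", {
  bp <- generate_beat_times(60, 72, hrv_sd = 0, seed = 2)
  rec <- synthesize_record(bp, fs = 100, noise = noise_off())
  win <- segment_windows(rec, preprocess_config())
  expect_true(all(abs(win$hr_bpm - 72) < 0.5))
})

test_that("outlier exclusion keeps the inclusive 35-120 BPM range", {
  win <- fake_windows(1, 5)
  win$hr_bpm <- c(34.9, 35.0, 75, 120.0, 120.1)
  kept <- suppressMessages(exclude_outliers(win, preprocess_config()))
  expect_equal(kept$hr_bpm, c(35.0, 75, 120.0))
  win$hr_bpm <- c(40, 60, 80, 100, 119)
  expect_equal(nrow(exclude_outliers(win, preprocess_config())), 5)
  win$hr_bpm[2] <- NA
  expect_equal(nrow(suppressMessages(exclude_outliers(win, preprocess_config()))), 4)
})

test_that("z-scoring uses the population deviation and is idempotent", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-4)
  expect_warning(zc <- zscore(rep(5, 10)), "constant")
  expect_equal(zc, rep(0, 10))
  set.seed(3)
  x <- rnorm(50, 10, 4)
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-9)
})

test_that("preprocessed windows satisfy their invariants at both native rates", {
  for (fs in c(100, 1000)) {
    bp <- generate_beat_times(20, 80, hrv_sd = 0.02, seed = 6)
    rec <- synthesize_record(bp, fs = fs, noise = noise_spec(seed = 6))
    win <- suppressMessages(preprocess_record(rec))
    expect_gt(nrow(win), 0)
    expect_true(all(vapply(win$bcg, function(w) all(dim(w) == c(400, 4)), logical(1))))
    expect_true(all(lengths(win$ppg) == 400))
    expect_true(all(win$hr_bpm >= 35 & win$hr_bpm <= 120))
    for (w in win$bcg[1:2]) {
      for (c in 1:4) {
        expect_lt(abs(mean(w[, c])), 1e-6)
        expect_equal(sqrt(mean((w[, c] - mean(w[, c]))^2)), 1, tolerance = 1e-6)
      }
    }
  }
})
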