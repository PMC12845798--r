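# Preprocessing pipeline: band-pass filtering at the native rate, polyphase
# resampling to 100 Hz, linear imputation of missing samples, ECG R-peak
# detection, 4 s / 1 s sliding-window segmentation with RR-derived labels,
# physiological outlier exclusion, and per-window z-scoring.

#' Preprocessing configuration
#'
#' @param fs_target Target sampling rate in Hz after resampling.
#' @param window_s Window length in seconds.
#' @param stride_s Window stride in seconds.
#' @param hr_min,hr_max Inclusive physiological label bounds in BPM.
#' @param bcg_band Band edges in Hz for the BCG (and PPG) channels.
#' @param ecg_band Band edges in Hz for the ECG channel.
#' @param refractory_s Minimum spacing between detected R-peaks in seconds.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(fs_target = 100, window_s = 4, stride_s = 1,
                              hr_min = 35, hr_max = 120,
                              bcg_band = c(0.3, 24), ecg_band = c(0.5, 40),
                              refractory_s = 0.25) {
  assert_that(abs(window_s * fs_target - round(window_s * fs_target)) < 1e-9,
              "`window_s * fs_target` must be an integer sample count")
  assert_that(hr_min < hr_max, "`hr_min` must be below `hr_max`")
  assert_that(max(bcg_band, ecg_band) < fs_target / 2,
              "filter band edges must lie below the target Nyquist frequency")
  structure(
    list(fs_target = fs_target, window_s = window_s, stride_s = stride_s,
         hr_min = hr_min, hr_max = hr_max, bcg_band = bcg_band,
         ecg_band = ecg_band, refractory_s = refractory_s),
    class = "preprocess_config"
  )
}

#' Zero-phase band-pass filter
#'
#' Cascaded order-4 Butterworth high-pass and low-pass sections, each
#' applied forward-backward (`signal::filtfilt`), so the passband is
#' preserved with zero phase distortion. The cascade (rather than a single
#' band-pass design) keeps the filter numerically stable when the band is
#' very narrow relative to the sampling rate, as for 0.3--24 Hz at 1 kHz.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, lo, hi) {
  assert_that(lo > 0 && lo < hi && hi < fs / 2,
              "band edges must satisfy 0 < lo < hi < fs/2")
  hp <- signal::butter(4, lo / (fs / 2), type = "high")
  lp <- signal::butter(4, hi / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x)))
}

#' Resample a signal down to a target rate
#'
#' Polyphase rational-rate resampling with anti-alias filtering
#' (`signal::resample`). Upsampling is out of scope.
#'
#' @param x Numeric vector.
#' @param fs_in Input sampling rate in Hz (>= `fs_target`).
#' @param fs_target Output sampling rate in Hz.
#' @return Vector of length `round(length(x) * fs_target / fs_in)`.
#' @export
resample_to_target <- function(x, fs_in, fs_target) {
  assert_that(fs_in >= fs_target,
              "`fs_in` must be at least `fs_target` (upsampling out of scope)")
  if (fs_in == fs_target) return(x)
  g <- gcd(round(fs_in), round(fs_target))
  p <- round(fs_target) / g
  q <- round(fs_in) / g
  y <- as.numeric(signal::resample(x, p, q))
  m <- round(length(x) * fs_target / fs_in)
  if (length(y) >= m) y[seq_len(m)] else c(y, rep(y[length(y)], m - length(y)))
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Linearly interpolate missing samples
#'
#' Interior `NA` runs are linearly interpolated between the flanking valid
#' samples; leading/trailing runs are filled with the nearest valid value.
#'
#' @param x Numeric vector with `NA` marking missing samples.
#' @return Vector with no missing values.
#' @export
interpolate_missing <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) stop_domain("cannot interpolate an all-missing signal")
  if (all(ok)) return(x)
  approx(x = which(ok), y = x[ok], xout = seq_along(x), rule = 2)$y
}

# Squared-derivative detection envelope with 150 ms moving integration.
detection_envelope <- function(ecg_f, fs) {
  d <- c(0, diff(ecg_f))
  sq <- d * d
  w <- max(3L, round(0.15 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  env <- stats::filter(sq, rep(1 / w, w), sides = 2)
  env <- as.numeric(env)
  env[!is.finite(env)] <- 0
  env
}

#' Detect ECG R-peaks
#'
#' Annotation-free detector in the spirit of classical QRS detection:
#' band-pass -> differentiate -> square -> 150 ms moving integration ->
#' adaptive threshold at half the rolling maximum of the envelope ->
#' refractory pruning keeping the larger candidate. Each returned index is
#' relocated to the local maximum of the band-passed ECG near the envelope
#' peak so the timing matches the R-wave apex.
#'
#' @param ecg Numeric ECG vector (at least one second of signal).
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum peak spacing in seconds.
#' @param band Detector band edges in Hz.
#' @return Strictly increasing integer sample indices (1-based); empty for
#'   a flat signal.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.25, band = c(0.5, 40)) {
  assert_that(length(ecg) > fs, "need at least one second of ECG signal")
  if (max(ecg) - min(ecg) < 1e-12) return(integer(0))
  ef <- bandpass(ecg, fs, band[1], band[2])
  env <- detection_envelope(ef, fs)
  k <- round(2 * fs)
  if (k %% 2L == 0L) k <- k + 1L
  thr <- 0.5 * zoo::rollmax(env, k, fill = "extend")
  n <- length(env)
  cand <- which(env > thr & env > 0)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[env[cand] >= env[cand - 1L] & env[cand] > env[cand + 1L]]
  if (length(cand) == 0) return(integer(0))
  # refractory pruning on the envelope, larger candidate wins
  refr <- refractory_s * fs
  kept <- cand[1]
  for (c in cand[-1]) {
    last <- kept[length(kept)]
    if (c - last < refr) {
      if (env[c] > env[last]) kept[length(kept)] <- c
    } else {
      kept <- c(kept, c)
    }
  }
  # relocate to the R-wave apex of the band-passed ECG
  half <- as.integer(round(0.1 * fs))
  peaks <- vapply(kept, function(i) {
    i0 <- max(1L, as.integer(i) - half)
    i1 <- min(n, as.integer(i) + half)
    i0 + which.max(ef[i0:i1]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # a second refractory pass in case relocation merged neighbours
  out <- peaks[1]
  for (p in peaks[-1]) {
    last <- out[length(out)]
    if (p - last < refr) {
      if (ef[p] > ef[last]) out[length(out)] <- p
    } else {
      out <- c(out, p)
    }
  }
  as.integer(out)
}

#' R-peak times with sub-sample refinement
#'
#' Converts detected R-peak indices to seconds, refining each location by
#' parabolic interpolation of the band-passed ECG around the apex. The
#' refinement keeps window labels accurate at 100 Hz, where plain sample
#' quantization is 10 ms.
#'
#' @inheritParams detect_r_peaks
#' @return Numeric peak times in seconds.
#' @export
r_peak_times <- function(ecg, fs, refractory_s = 0.25, band = c(0.5, 40)) {
  idx <- detect_r_peaks(ecg, fs, refractory_s, band)
  if (length(idx) == 0) return(numeric(0))
  ef <- bandpass(ecg, fs, band[1], band[2])
  n <- length(ef)
  delta <- vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(0)
    den <- ef[i - 1] - 2 * ef[i] + ef[i + 1]
    if (abs(den) < 1e-12) return(0)
    d <- 0.5 * (ef[i - 1] - ef[i + 1]) / den
    max(min(d, 0.5), -0.5)
  }, numeric(1))
  (idx - 1 + delta) / fs
}

#' Window heart rate from R-peak times
#'
#' The label is 60 divided by the mean RR interval of the peaks falling in
#' the window. Windows with fewer than two peaks are unlabeled (`NA`) and
#' excluded downstream.
#'
#' @param peak_times_in_window Numeric peak times (seconds) inside one window.
#' @return Heart rate in BPM, or `NA_real_` when fewer than two peaks.
#' @export
hr_from_window <- function(peak_times_in_window) {
  if (length(peak_times_in_window) < 2) return(NA_real_)
  60 / mean(diff(peak_times_in_window))
}

#' Segment a recording into labeled sliding windows
#'
#' Cuts `window_s`-second windows every `stride_s` seconds and labels each
#' from the mean RR interval of the ECG-detected R-peaks it contains. The
#' window count is `floor((N/fs - window_s)/stride_s) + 1` when the record
#' is at least one window long, else zero. Windows never span subjects.
#'
#' @param record A `signal_record` already at `cfg$fs_target`.
#' @param cfg A [preprocess_config()].
#' @param peak_times Optional pre-computed R-peak times in seconds; detected
#'   from `record$ecg` when omitted.
#' @return A tibble with columns `subject_id`, `t_start`, `hr_bpm` and
#'   list-columns `bcg` (L x 4 matrices) and `ppg` (length-L vectors),
#'   where L = `window_s * fs_target`.
#' @export
segment_windows <- function(record, cfg = preprocess_config(),
                            peak_times = NULL) {
  assert_that(abs(record$fs - cfg$fs_target) < 1e-6,
              "record must be resampled to `cfg$fs_target` before segmentation")
  fs <- cfg$fs_target
  n <- length(record$ecg)
  len <- as.integer(round(cfg$window_s * fs))
  stride <- cfg$stride_s * fs
  n_win <- if (n / fs >= cfg$window_s) {
    floor((n / fs - cfg$window_s) / cfg$stride_s) + 1
  } else 0
  if (n_win == 0) {
    return(tibble::tibble(subject_id = character(0), t_start = numeric(0),
                          hr_bpm = numeric(0), bcg = list(), ppg = list()))
  }
  if (is.null(peak_times)) {
    peak_times <- r_peak_times(record$ecg, fs, cfg$refractory_s, cfg$ecg_band)
  }
  starts <- (seq_len(n_win) - 1) * cfg$stride_s
  rows <- lapply(starts, function(t0) {
    i0 <- as.integer(round(t0 * fs)) + 1L
    idx <- i0:(i0 + len - 1L)
    pk <- peak_times[peak_times >= t0 & peak_times < t0 + cfg$window_s]
    list(t_start = t0, hr_bpm = hr_from_window(pk),
         bcg = record$bcg[idx, , drop = FALSE], ppg = record$ppg[idx])
  })
  tibble::tibble(
    subject_id = record$subject_id,
    t_start = vapply(rows, `[[`, numeric(1), "t_start"),
    hr_bpm = vapply(rows, `[[`, numeric(1), "hr_bpm"),
    bcg = lapply(rows, `[[`, "bcg"),
    ppg = lapply(rows, `[[`, "ppg")
  )
}

#' Drop windows with labels outside the physiological range
#'
#' Retains windows with `hr_min <= hr_bpm <= hr_max` (inclusive bounds:
#' only rates strictly outside the range are outliers). Unlabeled windows
#' (fewer than two detected beats) are dropped too; the number of removed
#' windows is reported via `message()`.
#'
#' @param windows Window tibble from [segment_windows()].
#' @param cfg A [preprocess_config()].
#' @return Filtered window tibble.
#' @export
exclude_outliers <- function(windows, cfg = preprocess_config()) {
  keep <- !is.na(windows$hr_bpm) &
    windows$hr_bpm >= cfg$hr_min & windows$hr_bpm <= cfg$hr_max
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf("excluded %d window(s): unlabeled or outside [%g, %g] BPM",
                    removed, cfg$hr_min, cfg$hr_max))
  }
  windows[keep, , drop = FALSE]
}

#' Z-score a window channel
#'
#' Standardizes to mean 0 and population standard deviation 1 (the
#' normalization removes inter-subject amplitude differences so the model
#' learns morphology, not absolute signal strength). A constant input maps
#' to all zeros with a warning.
#'
#' @param x Numeric vector (one channel of one window).
#' @return Standardized vector.
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) {
    warning("constant channel: z-score returned all zeros")
    return(rep(0, length(x)))
  }
  (x - m) / s
}

#' Z-score every channel of every window
#'
#' @param windows Window tibble.
#' @return Window tibble with standardized `bcg` and `ppg` list-columns.
#' @export
normalize_windows <- function(windows) {
  zs <- function(x) {
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s < 1e-12) rep(0, length(x)) else (x - m) / s
  }
  windows$bcg <- lapply(windows$bcg, function(w) apply(w, 2, zs))
  windows$ppg <- lapply(windows$ppg, zs)
  windows
}

#' Full preprocessing chain for one recording
#'
#' Stage order is fixed: band-pass at the native rate -> resample to the
#' target rate -> impute missing samples -> segment + label -> exclude
#' outliers -> z-score. (Raw `NA` samples are imputed before filtering as
#' well, since an IIR filter would otherwise propagate them.)
#'
#' @param record A `signal_record` at any rate >= `cfg$fs_target`.
#' @param cfg A [preprocess_config()].
#' @return Normalized, label-filtered window tibble.
#' @export
preprocess_record <- function(record, cfg = preprocess_config()) {
  guard <- function(x) if (anyNA(x)) interpolate_missing(x) else x
  fs <- record$fs
  bcg <- apply(record$bcg, 2, function(ch) {
    bandpass(guard(ch), fs, cfg$bcg_band[1], cfg$bcg_band[2])
  })
  ppg <- bandpass(guard(record$ppg), fs, cfg$bcg_band[1], cfg$bcg_band[2])
  ecg <- bandpass(guard(record$ecg), fs, cfg$ecg_band[1], cfg$ecg_band[2])

  bcg <- apply(bcg, 2, resample_to_target, fs_in = fs,
               fs_target = cfg$fs_target)
  ppg <- resample_to_target(ppg, fs, cfg$fs_target)
  ecg <- resample_to_target(ecg, fs, cfg$fs_target)

  bcg <- apply(bcg, 2, interpolate_missing)
  ppg <- interpolate_missing(ppg)
  ecg <- interpolate_missing(ecg)

  rec <- record
  rec$fs <- cfg$fs_target
  rec$bcg <- bcg
  rec$ppg <- ppg
  rec$ecg <- ecg
  win <- segment_windows(rec, cfg)
  win <- exclude_outliers(win, cfg)
  normalize_windows(win)
}

#' Preprocess a whole cohort
#'
#' @param cohort Cohort tibble (or list of `signal_record`s).
#' @param cfg A [preprocess_config()].
#' @return Window tibble pooled over subjects.
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config()) {
  records <- cohort_records(cohort)
  dplyr::bind_rows(lapply(records, preprocess_record, cfg = cfg))
}
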