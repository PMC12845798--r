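#' Generate a beat-time process with controlled rate and variability
#'
#' Draws a strictly increasing sequence of heartbeat instants whose
#' inter-beat (RR) intervals are `60/mean_hr` seconds plus independent
#' Gaussian jitter, truncated to the physiological range 0.3--2.0 s.
#' The first beat falls at t = 0 and beats beyond `duration_s` are dropped.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param mean_hr Target mean heart rate in BPM; must lie in the resting
#'   physiological range 35--120 BPM.
#' @param hrv_sd Standard deviation of the per-beat RR jitter in seconds.
#' @param seed Integer seed; the same seed reproduces the same process.
#' @return An object of class `beat_process`: a list with `beat_times`
#'   (seconds), `mean_hr` and `hrv_sd`.
#' @examples
#' bp <- generate_beat_times(10, 60, hrv_sd = 0, seed = 1)
#' bp$beat_times  # 0, 1, ..., 9
#' @export
generate_beat_times <- function(duration_s, mean_hr, hrv_sd = 0, seed = 1L) {
  assert_that(is.numeric(duration_s) && duration_s > 0,
              "`duration_s` must be positive")
  assert_that(mean_hr >= 35 && mean_hr <= 120,
              "`mean_hr` must lie in the resting physiological range [35, 120] BPM")
  assert_that(hrv_sd >= 0, "`hrv_sd` must be nonnegative")
  rr0 <- 60 / mean_hr
  n_max <- ceiling(duration_s / 0.3) + 2L
  rr <- with_seed(seed, {
    e <- rnorm(n_max, 0, hrv_sd)
    pmin(pmax(rr0 + e, 0.3), 2.0)
  })
  times <- cumsum(c(0, rr))
  times <- times[times < duration_s]
  structure(
    list(beat_times = times, mean_hr = mean_hr, hrv_sd = hrv_sd,
         duration_s = duration_s),
    class = "beat_process"
  )
}

#' Noise model for synthetic recordings
#'
#' Describes the disturbance sources layered on top of the clean per-beat
#' waveforms: broadband sensor noise, a low-frequency respiratory baseline
#' with amplitude modulation of the mechanical channel, and sparse
#' motion-artifact bursts of smoothed high-amplitude noise.
#'
#' @param white_sd Standard deviation of additive white noise (signal units;
#'   the clean BCG J-wave has unit amplitude).
#' @param respiration_hz Respiration frequency in Hz.
#' @param respiration_amp Amplitude of the additive respiratory baseline.
#' @param artifact_rate Expected motion-artifact events per minute.
#' @param artifact_amp Amplitude scale of artifact bursts.
#' @param seed Integer seed; identical spec + seed gives identical noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0.05, respiration_hz = 0.25,
                       respiration_amp = 0.2, artifact_rate = 2,
                       artifact_amp = 1.5, seed = 1L) {
  vals <- c(white_sd, respiration_hz, respiration_amp, artifact_rate, artifact_amp)
  assert_that(all(vals >= 0), "all noise parameters must be nonnegative")
  structure(
    list(white_sd = white_sd, respiration_hz = respiration_hz,
         respiration_amp = respiration_amp, artifact_rate = artifact_rate,
         artifact_amp = artifact_amp, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Silent noise model (all sources off)
#' @return A `noise_spec` with every amplitude zero.
#' @export
noise_off <- function() {
  noise_spec(white_sd = 0, respiration_amp = 0, artifact_rate = 0,
             artifact_amp = 0, seed = 0L)
}

# Three-lobe "IJK" kernel for the mechanical (BCG) beat complex: negative I
# lobe, dominant positive J lobe, negative K lobe, spanning about 150 ms.
bcg_kernel <- function(fs) {
  h <- round(0.075 * fs)
  tau <- (-h:h) / fs
  -0.4 * exp(-((tau + 0.030) / 0.012)^2) +
    1.0 * exp(-(tau / 0.015)^2) -
    0.6 * exp(-((tau - 0.035) / 0.015)^2)
}

# Smooth unimodal pulse for the optical (PPG) channel: raised cosine of
# about 300 ms total width, peak at tau = 0.
ppg_kernel <- function(fs) {
  h <- round(0.15 * fs)
  tau <- (-h:h) / fs
  0.5 * (1 + cos(pi * pmin(pmax(tau / 0.15, -1), 1)))
}

# Narrow positive spike marking the ECG R-wave (Gaussian, sigma ~ 10 ms).
ecg_kernel <- function(fs) {
  h <- round(0.04 * fs)
  tau <- (-h:h) / fs
  exp(-(tau / 0.010)^2)
}

# Place `kernel` at each event time (seconds) on an n-sample grid.
place_kernel <- function(n, fs, event_times, kernel) {
  out <- numeric(n)
  half <- (length(kernel) - 1L) %/% 2L
  for (tt in event_times) {
    centre <- round(tt * fs) + 1L
    i0 <- centre - half
    i1 <- centre + half
    k0 <- max(1L, 1L - i0 + 1L)
    k1 <- length(kernel) - max(0L, i1 - n)
    i0 <- max(1L, i0)
    i1 <- min(n, i1)
    if (i0 <= i1 && k0 <= k1) out[i0:i1] <- out[i0:i1] + kernel[k0:k1]
  }
  out
}

# Additive noise realization of length n (white + artifacts), plus the
# respiratory baseline, as a list; RNG state is the caller's.
noise_components <- function(n, fs, spec) {
  t <- (seq_len(n) - 1) / fs
  white <- if (spec$white_sd > 0) rnorm(n, 0, spec$white_sd) else numeric(n)
  phase <- runif(1, 0, 2 * pi)
  resp <- if (spec$respiration_amp > 0 && spec$respiration_hz > 0) {
    spec$respiration_amp * sin(2 * pi * spec$respiration_hz * t + phase)
  } else numeric(n)
  am <- 1 + 0.2 * sin(2 * pi * spec$respiration_hz * t + phase)
  burst <- numeric(n)
  if (spec$artifact_rate > 0 && spec$artifact_amp > 0) {
    n_ev <- rpois(1, spec$artifact_rate * n / fs / 60)
    if (n_ev > 0) {
      starts <- runif(n_ev, 0, n / fs)
      durs <- runif(n_ev, 0.5, 2.0)
      for (j in seq_len(n_ev)) {
        i0 <- max(1L, round(starts[j] * fs))
        i1 <- min(n, round((starts[j] + durs[j]) * fs))
        if (i1 <= i0) next
        raw <- rnorm(i1 - i0 + 1L, 0, spec$artifact_amp)
        # smooth the burst into colored noise
        burst[i0:i1] <- burst[i0:i1] +
          as.numeric(stats::filter(raw, 0.8, method = "recursive"))
      }
    }
  }
  list(white = white, resp = resp, am = am, burst = burst)
}

#' Synthesize a multi-channel recording from a beat process
#'
#' Renders synchronized ECG, 4-channel BCG and PPG traces at sampling rate
#' `fs`. The ECG is a narrow positive spike train at the beat times; each
#' BCG channel carries a three-lobe mechanical beat complex scaled by its
#' channel gain; the PPG is a smooth unimodal pulse delayed by the pulse
#' transit time `ptt_s`. Noise is layered per [noise_spec()]: white noise,
#' respiratory baseline (with +/-20% amplitude modulation of the BCG), and
#' sparse motion-artifact bursts. The reference ECG is left clean.
#'
#' @param beats A `beat_process` from [generate_beat_times()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param ptt_s Pulse transit time in seconds, in `[0, 0.4]`.
#' @param noise A [noise_spec()] applied to the BCG channels.
#' @param channel_gains Numeric length-4 gains for the BCG channels.
#' @param subject_id Identifier stored with the record.
#' @param ppg_noise Optional separate [noise_spec()] for the PPG channel;
#'   defaults to `noise`.
#' @param duration_s Recording length; defaults to the beat process length.
#' @return An object of class `signal_record` with elements `subject_id`,
#'   `fs`, `bcg` (N x 4 matrix), `ppg`, `ecg` (numeric vectors),
#'   `beat_times` and `ptt_s`.
#' @export
synthesize_record <- function(beats, fs = 100, ptt_s = 0.2,
                              noise = noise_spec(),
                              channel_gains = c(1, 0.9, 0.8, 0.7),
                              subject_id = "S1", ppg_noise = NULL,
                              duration_s = NULL) {
  assert_that(fs >= 100, "`fs` must be at least 100 Hz")
  assert_that(ptt_s >= 0 && ptt_s <= 0.4, "`ptt_s` must lie in [0, 0.4] s")
  assert_that(length(channel_gains) == 4, "`channel_gains` must have length 4")
  if (is.null(ppg_noise)) ppg_noise <- noise
  if (is.null(duration_s)) duration_s <- beats$duration_s
  n <- round(duration_s * fs)
  bt <- beats$beat_times
  if (length(bt) == 0) warning("empty beat sequence: record contains noise only")

  ecg <- place_kernel(n, fs, bt, ecg_kernel(fs))
  bcg1 <- place_kernel(n, fs, bt, bcg_kernel(fs))
  ppg1 <- place_kernel(n, fs, bt + ptt_s, ppg_kernel(fs))

  comp <- with_seed(noise$seed, noise_components(n, fs, noise))
  # per-channel white noise is independent but seeded, so records reproduce
  bcg <- with_seed(noise$seed + 1L, {
    vapply(seq_len(4), function(c) {
      w <- if (noise$white_sd > 0) rnorm(n, 0, noise$white_sd) else numeric(n)
      channel_gains[c] * bcg1 * comp$am + comp$resp + comp$burst + w
    }, numeric(n))
  })
  pcomp <- with_seed(ppg_noise$seed + 2L, noise_components(n, fs, ppg_noise))
  ppg <- ppg1 + pcomp$resp + pcomp$burst + pcomp$white

  structure(
    list(subject_id = subject_id, fs = fs, bcg = bcg, ppg = ppg, ecg = ecg,
         beat_times = bt, ptt_s = ptt_s),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> subject %s: %.1f s at %g Hz, %d beats, PTT %.3f s\n",
              x$subject_id, length(x$ecg) / x$fs, x$fs,
              length(x$beat_times), x$ptt_s))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject mean heart rate uniformly from `hr_range`, pulse
#' transit time uniformly from 0.15--0.30 s and slightly varied channel
#' gains, then synthesizes one recording per subject. Fully deterministic
#' under `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param duration_s Recording length per subject in seconds.
#' @param hr_range Length-2 BPM range for per-subject mean heart rates;
#'   must lie within `[35, 120]`.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @param hrv_sd Per-beat RR jitter standard deviation in seconds.
#' @param noise [noise_spec()] template for the BCG channels (per-subject
#'   seeds are derived from `seed`).
#' @param ppg_noise Optional separate noise template for the PPG channel.
#' @param out_dir Optional directory: when given, the cohort is also written
#'   as CSV signal files plus a manifest (see [write_cohort_csv()]).
#' @return A tibble with one row per subject: `subject_id`, `mean_hr`,
#'   `ptt_s`, `fs` and a `record` list-column of `signal_record` objects.
#' @examples
#' coh <- make_cohort(2, 30, hr_range = c(60, 80), seed = 1)
#' coh$subject_id
#' @export
make_cohort <- function(n_subjects, duration_s, hr_range = c(50, 100),
                        seed = 1L, fs = 100, hrv_sd = 0.03,
                        noise = noise_spec(), ppg_noise = NULL,
                        out_dir = NULL) {
  assert_that(n_subjects >= 1, "`n_subjects` must be at least 1")
  assert_that(length(hr_range) == 2 && hr_range[1] <= hr_range[2] &&
                hr_range[1] >= 35 && hr_range[2] <= 120,
              "`hr_range` must be an increasing pair within [35, 120] BPM")
  draws <- with_seed(seed, {
    list(
      hr = runif(n_subjects, hr_range[1], hr_range[2]),
      ptt = runif(n_subjects, 0.15, 0.30),
      gains = matrix(runif(4L * n_subjects, 0.7, 1.2), nrow = n_subjects),
      sub_seed = sample.int(1000000L, n_subjects)
    )
  })
  records <- lapply(seq_len(n_subjects), function(i) {
    bp <- generate_beat_times(duration_s, draws$hr[i], hrv_sd = hrv_sd,
                              seed = draws$sub_seed[i])
    ns <- noise
    ns$seed <- draws$sub_seed[i] + 13L
    ps <- if (is.null(ppg_noise)) ns else {
      tmp <- ppg_noise
      tmp$seed <- draws$sub_seed[i] + 29L
      tmp
    }
    synthesize_record(bp, fs = fs, ptt_s = draws$ptt[i], noise = ns,
                      channel_gains = draws$gains[i, ],
                      subject_id = sprintf("S%02d", i), ppg_noise = ps)
  })
  cohort <- tibble::tibble(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    mean_hr = draws$hr,
    ptt_s = draws$ptt,
    fs = fs,
    record = records
  )
  if (!is.null(out_dir)) write_cohort_csv(cohort, out_dir)
  cohort
}
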