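# Synthetic single-lead ECG and contamination generator. The clean waveform is
# the standard sum-of-Gaussians PQRST phantom; contamination covers the four
# canonical ECG noise families at a requested signal-to-noise ratio.

# P, Q, R, S, T bump parameters: center offset from the R wave (s),
# amplitude (relative to R = 1), and Gaussian width (s).
pqrst_shape <- function() {
  list(
    center = c(p = -0.200, q = -0.035, r = 0.000, s = 0.035, t = 0.280),
    amp    = c(p =  0.140, q = -0.120, r = 1.000, s = -0.250, t = 0.320),
    width  = c(p =  0.028, q =  0.010, r = 0.013, s =  0.012, t = 0.060)
  )
}

#' Generate a clean synthetic single-lead ECG
#'
#' One Gaussian bump per P, Q, R, S and T wave is placed around each beat;
#' beat-to-beat (RR) intervals jitter uniformly within +/-4% of the nominal
#' period. Amplitudes are on the order of 1 (R wave = 1). Useful as the
#' acceptable-quality reference for exercising the quality classifier without
#' any external recordings.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param heart_rate_bpm Mean heart rate, 30-220 beats/min.
#' @param seed Integer seed; output is bitwise reproducible for a fixed seed.
#' @param id,lead_id,group_id Identifiers for the returned record.
#' @return One-row `ecg_tbl` holding `round(duration_s * fs)` samples.
#' @examples
#' rec <- make_clean_ecg(10, 500, 60, seed = 1)
#' length(rec$samples[[1]])
#' @export
make_clean_ecg <- function(duration_s = 10, fs = 500, heart_rate_bpm = 60,
                           seed = 1L, id = "synth1", lead_id = "lead1",
                           group_id = id) {
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  check_scalar_number(fs, "fs", positive = TRUE)
  check_scalar_number(heart_rate_bpm, "heart_rate_bpm", positive = TRUE)
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220) {
    abort("`heart_rate_bpm` must lie in [30, 220].", class = "ecgsqa_invalid_argument")
  }
  x <- with_seed(seed, clean_ecg_wave(duration_s, fs, heart_rate_bpm))
  ecg_corpus(list(x), fs = fs, id = id, lead_id = lead_id, group_id = group_id)
}

clean_ecg_wave <- function(duration_s, fs, heart_rate_bpm) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  rr <- 60 / heart_rate_bpm
  # Lay out jittered R-peak times covering the record plus one beat margin.
  n_beats <- ceiling(duration_s / rr) + 2L
  jitter <- stats::runif(n_beats, -0.04, 0.04)
  intervals <- rr * (1 + jitter)
  r_times <- cumsum(c(-rr / 2, intervals[-1]))
  shape <- pqrst_shape()
  x <- numeric(n)
  for (b in seq_along(r_times)) {
    for (w in seq_along(shape$center)) {
      mu <- r_times[b] + shape$center[w]
      sd <- shape$width[w]
      # Gaussians are negligible beyond 5 sd; restrict for speed.
      lo <- max(1L, floor((mu - 5 * sd) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * sd) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + shape$amp[w] * exp(-0.5 * ((t[idx] - mu) / sd)^2)
    }
  }
  x
}

#' Specify a contamination source
#'
#' The four canonical ECG noise families plus a random composite:
#' \describe{
#'   \item{baseline_wander}{a slow sinusoid, 0.15-0.5 Hz (respiration-range drift)}
#'   \item{powerline}{a pure 50 or 60 Hz tone}
#'   \item{emg}{band-limited white noise, 20-120 Hz (muscle activity)}
#'   \item{electrode_motion}{random baseline steps and decaying spike transients}
#'   \item{composite}{a random mixture of the four families}
#' }
#'
#' @param kind One of `"baseline_wander"`, `"powerline"`, `"emg"`,
#'   `"electrode_motion"`, `"composite"`.
#' @param target_snr_db Requested signal-to-noise ratio in dB
#'   (`10 * log10(P_signal / P_noise)`); `Inf` means no noise is added.
#' @param powerline_hz Mains frequency, 50 or 60 Hz.
#' @param seed Integer seed for the noise realization.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(kind = c("composite", "baseline_wander", "powerline",
                                "emg", "electrode_motion"),
                       target_snr_db = 0, powerline_hz = 50, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(target_snr_db) || length(target_snr_db) != 1L || is.na(target_snr_db)) {
    abort("`target_snr_db` must be a single number (possibly Inf).",
          class = "ecgsqa_invalid_argument")
  }
  if (!powerline_hz %in% c(50, 60)) {
    abort("`powerline_hz` must be 50 or 60.", class = "ecgsqa_invalid_argument")
  }
  structure(list(kind = kind, target_snr_db = as.numeric(target_snr_db),
                 powerline_hz = powerline_hz, seed = as.integer(seed)),
            class = "noise_spec")
}

# Unit-scale noise realizations; power is normalized afterwards.
noise_wave <- function(kind, n, fs, powerline_hz) {
  t <- (seq_len(n) - 1L) / fs
  switch(kind,
    baseline_wander = {
      f <- stats::runif(1, 0.15, 0.5)
      sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    },
    powerline = sin(2 * pi * powerline_hz * t + stats::runif(1, 0, 2 * pi)),
    emg = bandlimited_noise(n, fs, 20, 120),
    electrode_motion = motion_artifact(n, fs),
    composite = {
      kinds <- c("baseline_wander", "powerline", "emg", "electrode_motion")
      wts <- stats::runif(4, 0.2, 1)
      parts <- lapply(kinds, noise_wave, n = n, fs = fs, powerline_hz = powerline_hz)
      Reduce(`+`, Map(function(w, p) w * p / max(stats::sd(p), 1e-12), wts, parts))
    }
  )
}

# White noise restricted to [lo, hi] Hz by zeroing FFT bins outside the band.
bandlimited_noise <- function(n, fs, lo, hi) {
  z <- stats::fft(stats::rnorm(n))
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  z[freq < lo | freq > hi] <- 0
  Re(stats::fft(z, inverse = TRUE)) / n
}

# A few abrupt baseline steps and exponentially decaying spikes.
motion_artifact <- function(n, fs) {
  x <- numeric(n)
  n_events <- max(1L, stats::rpois(1, 3))
  for (i in seq_len(n_events)) {
    pos <- sample.int(n, 1)
    amp <- stats::runif(1, 0.5, 2) * sample(c(-1, 1), 1)
    if (stats::runif(1) < 0.5) {
      x[pos:n] <- x[pos:n] + amp          # step
    } else {
      len <- min(n - pos + 1L, round(0.3 * fs))
      x[pos:(pos + len - 1L)] <- x[pos:(pos + len - 1L)] +
        amp * exp(-(0:(len - 1L)) / (0.05 * fs))  # decaying spike
    }
  }
  x
}

#' Add contamination at a controlled SNR
#'
#' Scales a noise realization so that the realized signal-to-noise ratio
#' `10 * log10(P_signal / P_noise)` equals `spec$target_snr_db` exactly
#' (power is matched analytically, not stochastically). Record length and
#' sampling rate are unchanged; `target_snr_db = Inf` returns the input
#' untouched.
#'
#' @param data An ECG corpus tibble; noise is added to every row.
#' @param spec A [noise_spec()]. Rows receive independent realizations
#'   (seeded from `spec$seed`, so repeated calls are bitwise identical).
#' @return The corpus with contaminated `samples` and a `snr_db` column of
#'   realized SNRs (`Inf` where untouched).
#' @examples
#' rec <- make_clean_ecg(10, 500, 60, seed = 1)
#' noisy <- add_noise(rec, noise_spec("powerline", target_snr_db = 0))
#' @export
add_noise <- function(data, spec) {
  data <- as_ecg_tbl(data)
  if (!inherits(spec, "noise_spec")) {
    abort("`spec` must be created with noise_spec().", class = "ecgsqa_invalid_argument")
  }
  if (is.infinite(spec$target_snr_db) && spec$target_snr_db > 0) {
    data$snr_db <- Inf
    return(data)
  }
  out <- with_seed(spec$seed, {
    purrr::map2(data$samples, data$fs, function(x, fs) {
      nz <- noise_wave(spec$kind, length(x), fs, spec$powerline_hz)
      p_n <- signal_power(nz)
      if (p_n == 0) return(x)  # degenerate zero-amplitude noise: passthrough
      scale <- sqrt(signal_power(x) / (p_n * 10^(spec$target_snr_db / 10)))
      x + scale * nz
    })
  })
  data$samples <- out
  data$snr_db <- rep(spec$target_snr_db, nrow(data))
  data
}

#' Generate a labeled synthetic corpus at a controlled class ratio
#'
#' Emulates the study conditions of a quality-labeled single-lead corpus:
#' 10-s records at `fs` Hz, `round(n * ratio_acceptable)` of them acceptable
#' (clean, or contaminated at a high SNR) and the remainder unacceptable
#' (heavily contaminated with a random mixture of noise families). Each
#' record carries a unique `group_id`, so group-aware splitting is exercised.
#'
#' @param n Number of records (>= 2).
#' @param ratio_acceptable Fraction of acceptable records, in (0, 1).
#' @param fs Sampling rate in Hz.
#' @param snr_acceptable_db Minimum SNR (dB) of contaminated acceptable
#'   records; acceptable SNRs are drawn uniformly in
#'   `[snr_acceptable_db, snr_acceptable_db + 10]` and half the class is left
#'   clean.
#' @param snr_unacceptable_db Maximum SNR (dB) of unacceptable records; their
#'   SNRs are drawn uniformly in `[snr_unacceptable_db - 10, snr_unacceptable_db]`.
#' @param seed Integer seed; the corpus is bitwise reproducible.
#' @param duration_s Record duration in seconds.
#' @param keep_clean Keep the uncontaminated reference waveform in a
#'   `clean` list-column (for SNR auditing).
#' @return An `ecg_tbl` with `label` and realized `snr_db` columns.
#' @examples
#' corp <- make_labeled_corpus(10, 0.5, seed = 1)
#' class_ratio(corp)
#' @export
make_labeled_corpus <- function(n, ratio_acceptable = 0.5, fs = 500,
                                snr_acceptable_db = 10, snr_unacceptable_db = 0,
                                seed = 1L, duration_s = 10, keep_clean = FALSE) {
  check_scalar_number(n, "n", positive = TRUE)
  if (n < 2) abort("`n` must be at least 2.", class = "ecgsqa_invalid_argument")
  if (ratio_acceptable <= 0 || ratio_acceptable >= 1) {
    abort("`ratio_acceptable` must lie strictly between 0 and 1.",
          class = "ecgsqa_invalid_argument")
  }
  if (snr_acceptable_db <= snr_unacceptable_db) {
    abort("`snr_acceptable_db` must exceed `snr_unacceptable_db`.",
          class = "ecgsqa_invalid_argument")
  }
  n <- as.integer(n)
  n_acc <- as.integer(round(n * ratio_acceptable))
  labels <- c(rep("acceptable", n_acc), rep("unacceptable", n - n_acc))
  kinds <- c("baseline_wander", "powerline", "emg", "electrode_motion", "composite")

  with_seed(seed, {
    hr <- stats::runif(n, 50, 100)
    clean_flag <- labels == "acceptable" & (seq_len(n) %% 2L == 1L)
    snr <- ifelse(labels == "acceptable",
                  stats::runif(n, snr_acceptable_db, snr_acceptable_db + 10),
                  stats::runif(n, snr_unacceptable_db - 10, snr_unacceptable_db))
    snr[clean_flag] <- Inf
    kind <- sample(kinds, n, replace = TRUE)
    mains <- sample(c(50, 60), n, replace = TRUE)
    clean <- lapply(seq_len(n), function(i) clean_ecg_wave(duration_s, fs, hr[i]))
    samples <- lapply(seq_len(n), function(i) {
      x <- clean[[i]]
      if (is.infinite(snr[i])) return(x)
      nz <- noise_wave(kind[i], length(x), fs, mains[i])
      p_n <- signal_power(nz)
      x + sqrt(signal_power(x) / (p_n * 10^(snr[i] / 10))) * nz
    })
    out <- ecg_corpus(samples, fs = fs,
                      id = sprintf("synth%05d", seq_len(n)),
                      group_id = sprintf("grp%05d", seq_len(n)),
                      label = labels)
    out$snr_db <- snr
    out$noise_kind <- ifelse(is.infinite(snr), "none", kind)
    if (keep_clean) out$clean <- clean
    out
  })
}
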