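# Short-time Fourier transform magnitude spectrograms: the classifier's
# input representation.

#' Periodic Hann window
#'
#' `w[n] = 0.5 - 0.5 * cos(2 * pi * n / N)` for `n = 0, ..., N - 1`. The
#' denominator is N (periodic form), so `w[0] = 0` and, for even N, the
#' center weight `w[N/2] = 1`.
#'
#' @param N Window length in samples (>= 2).
#' @return Numeric vector of N weights.
#' @examples
#' hann_window(8)[c(1, 3, 5)]  # 0, 0.5, 1
#' @export
hann_window <- function(N) {
  check_scalar_number(N, "N", positive = TRUE)
  if (N < 2) abort("`N` must be at least 2.", class = "ecgsqa_invalid_argument")
  n <- seq_len(N) - 1L
  0.5 - 0.5 * cos(2 * pi * n / N)
}

#' STFT analysis parameters
#'
#' Frame length and frame step (hop) of the analysis window. The defaults,
#' 256 and 128 samples, are the conventional power-of-two pair under which a
#' 10-s, 500-Hz segment (5000 samples) yields a 38 x 129 spectrogram:
#' 129 = 256/2 + 1 one-sided bins and 38 = floor((5000 - 256)/128) + 1 frames.
#'
#' @param frame_length Analysis window length in samples (even, >= 2).
#' @param frame_step Hop between successive frames, `0 < step <= length`.
#' @return An `stft_params` list.
#' @export
stft_params <- function(frame_length = 256L, frame_step = 128L) {
  check_scalar_number(frame_length, "frame_length", positive = TRUE)
  check_scalar_number(frame_step, "frame_step", positive = TRUE)
  frame_length <- as.integer(frame_length)
  frame_step <- as.integer(frame_step)
  if (frame_length %% 2L != 0L) {
    abort("`frame_length` must be even.", class = "ecgsqa_invalid_argument")
  }
  if (frame_step > frame_length) {
    abort("`frame_step` must not exceed `frame_length`.", class = "ecgsqa_invalid_argument")
  }
  structure(list(frame_length = frame_length, frame_step = frame_step,
                 window = "hann"),
            class = "stft_params")
}

#' Magnitude spectrogram of a signal
#'
#' Splits the signal into frames of `frame_length` samples advancing by
#' `frame_step` (frame `f` covers samples `[(f-1)*step + 1, (f-1)*step +
#' frame_length]`), tapers each frame with the periodic Hann window, applies
#' the FFT, and keeps the magnitude of the one-sided spectrum
#' (`frame_length/2 + 1` bins). No padding: the final partial frame is
#' dropped, so `T = floor((L - frame_length)/frame_step) + 1`.
#'
#' @param x Numeric signal of length >= `frame_length`.
#' @param params An [stft_params()] object.
#' @return A `T x F` nonnegative matrix of class `ecg_spectrogram` with the
#'   parameters attached as attributes.
#' @examples
#' sp <- stft_magnitude(sin(2 * pi * 25 * (0:4999) / 500), stft_params())
#' dim(sp)  # 38 129
#' @export
stft_magnitude <- function(x, params = stft_params()) {
  if (!inherits(params, "stft_params")) {
    abort("`params` must be created with stft_params().", class = "ecgsqa_invalid_argument")
  }
  if (!is.numeric(x) || length(x) < params$frame_length) {
    abort(sprintf("Signal shorter than one frame (%d < %d samples).",
                  length(x), params$frame_length),
          class = "ecgsqa_invalid_argument")
  }
  flen <- params$frame_length
  step <- params$frame_step
  n_frames <- (length(x) - flen) %/% step + 1L
  # Frames as columns of a flen x T matrix, windowed, then one FFT per column.
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * step, `+`)
  frames <- matrix(x[idx], nrow = flen) * hann_window(flen)
  spec <- stats::mvfft(frames)
  mag <- t(Mod(spec[seq_len(flen %/% 2L + 1L), , drop = FALSE]))
  structure(mag, class = c("ecg_spectrogram", "matrix", "array"),
            frame_length = flen, frame_step = step, window = "hann")
}

#' Convert a fixed-length record to the classifier's input
#'
#' Composition of amplitude normalization to [-1, 1] and [stft_magnitude()].
#' The record must already be at the configured rate and duration (default
#' 10 s at 500 Hz); anything else is a shape error, because the classifier's
#' input layer is fixed at (frames, bins) = (38, 129) under the default
#' parameters.
#'
#' @param data A one-row ECG corpus tibble (or a corpus; see
#'   [ecg_spectrograms()] for the vectorized verb).
#' @param params An [stft_params()] object.
#' @param expected_fs,window_s Required sampling rate (Hz) and duration (s).
#' @return An `ecg_spectrogram` matrix.
#' @export
to_model_input <- function(data, params = stft_params(), expected_fs = 500,
                           window_s = 10) {
  data <- as_ecg_tbl(data)
  if (nrow(data) != 1L) {
    abort("`to_model_input()` takes a single record; use ecg_spectrograms() for a corpus.",
          class = "ecgsqa_invalid_argument")
  }
  n_expected <- round(window_s * expected_fs)
  n <- length(data$samples[[1]])
  if (data$fs[1] != expected_fs || n != n_expected) {
    abort(sprintf(
      "Record `%s` has %d samples at %g Hz; the model expects %d samples at %g Hz (%g s). Resample/segment first.",
      data$id[1], n, data$fs[1], n_expected, expected_fs, window_s),
      class = "ecgsqa_shape_error")
  }
  stft_magnitude(normalize_signal(data$samples[[1]]), params)
}

#' Attach spectrograms to a corpus
#'
#' Adds a `spectrogram` list-column holding [to_model_input()] of every row.
#'
#' @inheritParams to_model_input
#' @param data An ECG corpus tibble of fixed-length segments.
#' @return The corpus with a `spectrogram` list-column.
#' @export
ecg_spectrograms <- function(data, params = stft_params(), expected_fs = 500,
                             window_s = 10) {
  data <- as_ecg_tbl(data)
  data$spectrogram <- lapply(seq_len(nrow(data)), function(i) {
    to_model_input(data[i, ], params, expected_fs, window_s)
  })
  data
}

#' Plot a spectrogram
#'
#' Time-frequency heat map of the magnitude spectrogram (log10 color scale).
#'
#' @param object An `ecg_spectrogram`.
#' @param fs Sampling rate used to label the axes (Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_spectrogram
#' @export
autoplot.ecg_spectrogram <- function(object, fs = 500, ...) {
  step <- attr(object, "frame_step")
  flen <- attr(object, "frame_length")
  df <- expand.grid(frame = seq_len(nrow(object)), bin = seq_len(ncol(object)))
  df$time_s <- ((df$frame - 1) * step + flen / 2) / fs
  df$freq_hz <- (df$bin - 1) * fs / flen
  df$magnitude <- as.vector(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = log10(.data$magnitude + 1e-6))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 |X|") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}
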