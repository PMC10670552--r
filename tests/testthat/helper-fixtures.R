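# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, fast model configuration for smoke tests (full-size defaults are
# exercised in the acceptance tests).
tiny_model_config <- function(epochs = 4L, ...) {
  model_config(conv_blocks = list(c(8L, 3L), c(16L, 3L)),
               dense_units = 16L, lstm_units = 16L, head_units = 8L,
               epochs = epochs, patience = Inf, ...)
}

# Labeled synthetic corpus with spectrograms attached.
spectro_corpus <- function(n, ratio = 0.5, seed = 1L, snr_gap = c(10, -10)) {
  corp <- make_labeled_corpus(n, ratio,
                              snr_acceptable_db = snr_gap[1],
                              snr_unacceptable_db = snr_gap[2],
                              seed = seed)
  ecg_spectrograms(corp)
}

# Brute-force O(N^2) windowed DFT per frame: the independent oracle for
# stft_magnitude(). Direct summation, no FFT.
dft_oracle <- function(x, frame_length, frame_step) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(frame_length) - 1) / frame_length)
  n_frames <- (length(x) - frame_length) %/% frame_step + 1L
  n_bins <- frame_length %/% 2L + 1L
  out <- matrix(0, n_frames, n_bins)
  for (f in seq_len(n_frames)) {
    xf <- x[(f - 1L) * frame_step + seq_len(frame_length)] * w
    for (b in seq_len(n_bins)) {
      k <- seq_len(frame_length) - 1L
      out[f, b] <- Mod(sum(xf * exp(-2i * pi * k * (b - 1L) / frame_length)))
    }
  }
  out
}

# Count R peaks: local maxima above half the global maximum, separated by a
# 0.3-s refractory window.
count_r_peaks <- function(x, fs) {
  thr <- max(x) / 2
  refractory <- round(0.3 * fs)
  peaks <- which(x > thr &
                   x >= c(-Inf, x[-length(x)]) &
                   x >= c(x[-1], -Inf))
  if (length(peaks) == 0L) return(0L)
  kept <- peaks[1]
  for (p in peaks[-1]) {
    if (p - kept[length(kept)] > refractory) kept <- c(kept, p)
  }
  length(kept)
}

# Realized SNR (dB) of a contaminated record against its clean reference.
realized_snr <- function(noisy, clean) {
  resid <- noisy - clean
  10 * log10(mean(clean^2) / mean(resid^2))
}
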