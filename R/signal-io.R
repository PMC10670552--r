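# Waveform input, resampling, amplitude normalization and labeled-region
# segmentation into fixed-length training windows.

#' Read an ECG waveform file
#'
#' Reads either delimited text (one column per lead, whitespace- or
#' comma-separated, header optional) or a WAV file (PCM 16/32-bit or IEEE
#' float, any channel count). Each detected lead becomes one corpus row; all
#' leads share `group_id = ` the file stem, so group-aware splitting keeps a
#' multi-lead recording together.
#'
#' @param path Path to a waveform file.
#' @param fs_hint Sampling rate in Hz for text input (WAV carries its own
#'   rate in the header). Required for text files.
#' @return An `ecg_tbl` with one row per lead.
#' @export
read_waveform <- function(path, fs_hint = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ecgsqa_format_error")
  }
  if (file.size(path) == 0) {
    abort(sprintf("Empty waveform file: %s", path), class = "ecgsqa_format_error")
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && rawToChar(magic) == "RIFF") {
    wav <- read_wav(path)
    mat <- wav$samples
    fs <- wav$fs
  } else {
    mat <- read_delimited_leads(path)
    if (is.null(fs_hint)) {
      abort("Text waveforms carry no sampling rate; supply `fs_hint`.",
            class = "ecgsqa_missing_rate_error")
    }
    check_scalar_number(fs_hint, "fs_hint", positive = TRUE)
    fs <- fs_hint
  }
  n_leads <- ncol(mat)
  ecg_corpus(lapply(seq_len(n_leads), function(j) mat[, j]),
             fs = fs,
             id = sprintf("%s_lead%d", stem, seq_len(n_leads)),
             lead_id = sprintf("lead%d", seq_len(n_leads)),
             group_id = stem)
}

# Sniff the delimiter from the first data line; header rows are skipped.
read_delimited_leads <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first))) {
    abort(sprintf("No data in waveform file: %s", path), class = "ecgsqa_format_error")
  }
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(probe)))
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header, comment.char = "",
                      strip.white = TRUE),
    error = function(e) abort(sprintf("Cannot parse waveform file %s: %s",
                                      path, conditionMessage(e)),
                              class = "ecgsqa_format_error")
  )
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  if (nrow(mat) == 0L || anyNA(mat)) {
    abort(sprintf("Non-numeric or empty waveform data in %s.", path),
          class = "ecgsqa_format_error")
  }
  mat
}

# --- Minimal RIFF/WAV codec (PCM 16/32-bit and IEEE float 32/64) -----------
# Returns list(samples = <n x channels matrix>, fs).
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("Not a WAV file: %s", path), class = "ecgsqa_format_error")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        fs = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("WAV file %s lacks fmt/data chunks.", path), class = "ecgsqa_format_error")
  }
  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- if (fmt$format == 1L) {          # integer PCM
    if (!fmt$bits %in% c(16L, 32L)) {
      abort(sprintf("Unsupported PCM bit depth %d in %s.", fmt$bits, path),
            class = "ecgsqa_format_error")
    }
    readBin(data_raw, "integer", n_total, size = bytes, endian = "little") /
      2^(fmt$bits - 1L)
  } else if (fmt$format == 3L) {        # IEEE float
    readBin(data_raw, "double", n_total, size = bytes, endian = "little")
  } else {
    abort(sprintf("Unsupported WAV format code %d in %s.", fmt$format, path),
          class = "ecgsqa_format_error")
  }
  n_frames <- n_total %/% fmt$channels
  list(samples = matrix(x[seq_len(n_frames * fmt$channels)],
                        nrow = n_frames, ncol = fmt$channels, byrow = TRUE),
       fs = fmt$fs)
}

#' Write a WAV file
#'
#' Companion writer for [read_waveform()]'s WAV branch; IEEE float-32 frames
#' (no amplitude quantization) or 16-bit PCM.
#'
#' @param samples Numeric vector or n-x-channels matrix.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @param bits 32 (IEEE float, default) or 16 (PCM; input must be in [-1, 1]).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bits = 32L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  channels <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  if (bits == 32L) {
    fmt_code <- 3L
    payload_size <- length(interleaved) * 4L
  } else if (bits == 16L) {
    fmt_code <- 1L
    payload_size <- length(interleaved) * 2L
  } else {
    abort("`bits` must be 16 or 32.", class = "ecgsqa_invalid_argument")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(channels, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * channels * bits / 8), con, size = 4, endian = "little")
  writeBin(as.integer(channels * bits / 8), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_size), con, size = 4, endian = "little")
  if (bits == 32L) {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

# --- Resampling ------------------------------------------------------------

# Band-limited (Fourier-domain) resampling: the spectrum is truncated (down)
# or zero-padded (up) so no aliasing is introduced and band-limited content
# is preserved exactly up to boundary effects. Phase-neutral: no filter
# delay to compensate.
resample_signal <- function(x, fs, target_fs) {
  if (target_fs == fs) return(x)
  n_in <- length(x)
  n_out <- round(n_in * target_fs / fs)
  X <- stats::fft(x)
  half <- min(n_in, n_out) %/% 2L
  Y <- complex(n_out)
  Y[1] <- X[1]
  if (half >= 1L) {
    Y[2:(half + 1L)] <- X[2:(half + 1L)]
    Y[n_out - seq_len(half) + 1L] <- X[n_in - seq_len(half) + 1L]
  }
  # keep the Nyquist bin real when both lengths are even
  if (min(n_in, n_out) %% 2L == 0L && half >= 1L) {
    Y[half + 1L] <- Re(Y[half + 1L])
    if (n_out > n_in) Y[n_out - half + 1L] <- Re(Y[n_out - half + 1L])
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n_in)
}

#' Resample records to a target rate
#'
#' Band-limited polyphase resampling (anti-aliased), as opposed to naive
#' decimation. Output length is `round(length * target_fs / fs)` per record.
#'
#' @param data An ECG corpus tibble.
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return The corpus with resampled `samples` and updated `fs`.
#' @examples
#' rec <- make_clean_ecg(10, 1000, 60, seed = 1)
#' ecg_resample(rec, 500)$fs
#' @export
ecg_resample <- function(data, target_fs) {
  data <- as_ecg_tbl(data)
  check_scalar_number(target_fs, "target_fs", positive = TRUE)
  data$samples <- purrr::map2(data$samples, data$fs, resample_signal,
                              target_fs = target_fs)
  data$fs <- rep(as.numeric(target_fs), nrow(data))
  data
}

# --- Amplitude normalization ----------------------------------------------

normalize_signal <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(numeric(length(x)))  # constant -> all zeros
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Min-max normalize record amplitudes to [-1, 1]
#'
#' Applies `x -> 2 * (x - min) / (max - min) - 1` per record, so every
#' non-constant record attains exactly -1 and +1. A constant record maps to
#' all zeros. Normalization is applied per 10-s segment (after
#' segmentation), matching what the classifier consumes.
#'
#' @param data An ECG corpus tibble.
#' @return The corpus with normalized `samples`.
#' @export
ecg_normalize <- function(data) {
  data <- as_ecg_tbl(data)
  data$samples <- purrr::map(data$samples, normalize_signal)
  data
}

# --- Labeled-region segmentation ------------------------------------------

#' Cut labeled regions into fixed-length training windows
#'
#' Each annotated region of a record is cut into
#' `floor(region_duration / window_s)` consecutive non-overlapping windows
#' anchored at the region start, every window inheriting the region's label
#' and the record's `group_id`. The tail remainder, and any region shorter
#' than `window_s`, is discarded.
#'
#' @param data An ECG corpus tibble (labels on the corpus rows are ignored;
#'   the region labels rule).
#' @param regions A data frame with columns `id` (matching corpus rows, or
#'   absent/`NA` when `data` has a single record), `start_s`, `end_s`,
#'   `label`. Regions must lie within the record and not overlap.
#' @param window_s Window length in seconds (default 10).
#' @return An `ecg_tbl` of labeled windows (`<record id>_w<k>`).
#' @examples
#' rec <- make_clean_ecg(25, 500, 60, seed = 1)
#' regions <- tibble::tibble(start_s = 0, end_s = 25, label = "acceptable")
#' nrow(segment_labeled(rec, regions))  # floor(25 / 10) = 2
#' @export
segment_labeled <- function(data, regions, window_s = 10) {
  data <- as_ecg_tbl(data)
  check_scalar_number(window_s, "window_s", positive = TRUE)
  if (!is.data.frame(regions) || !all(c("start_s", "end_s", "label") %in% names(regions))) {
    abort("`regions` needs columns start_s, end_s, label.", class = "ecgsqa_data_error")
  }
  if (!"id" %in% names(regions)) {
    if (nrow(data) != 1L) {
      abort("`regions` needs an `id` column when `data` has several records.",
            class = "ecgsqa_data_error")
    }
    regions$id <- data$id
  }
  regions$label <- as_quality(regions$label)
  if (any(regions$end_s <= regions$start_s)) {
    abort("Every region must satisfy end_s > start_s.", class = "ecgsqa_data_error")
  }

  pieces <- lapply(seq_len(nrow(data)), function(i) {
    rec <- data[i, ]
    reg <- regions[regions$id == rec$id, , drop = FALSE]
    if (nrow(reg) == 0L) return(NULL)
    reg <- reg[order(reg$start_s), , drop = FALSE]
    dur <- length(rec$samples[[1]]) / rec$fs
    if (any(reg$start_s < 0) || any(reg$end_s > dur + 1e-9)) {
      abort(sprintf("Region outside record `%s` (duration %.3f s).", rec$id, dur),
            class = "ecgsqa_data_error")
    }
    if (nrow(reg) > 1L && any(reg$start_s[-1] < reg$end_s[-nrow(reg)] - 1e-9)) {
      abort(sprintf("Overlapping regions in record `%s`.", rec$id),
            class = "ecgsqa_data_error")
    }
    win_n <- round(window_s * rec$fs)
    out <- list()
    k <- 0L
    for (r in seq_len(nrow(reg))) {
      n_win <- floor((reg$end_s[r] - reg$start_s[r]) / window_s)
      if (n_win < 1) next  # shorter than one window: discarded
      start_idx <- round(reg$start_s[r] * rec$fs)
      for (w in seq_len(n_win)) {
        k <- k + 1L
        idx <- start_idx + (w - 1L) * win_n + seq_len(win_n)
        out[[k]] <- tibble::tibble(
          id = sprintf("%s_w%d", rec$id, k),
          samples = list(rec$samples[[1]][idx]),
          fs = rec$fs, lead_id = rec$lead_id, group_id = rec$group_id,
          label = reg$label[r]
        )
      }
    }
    if (k == 0L) NULL else dplyr::bind_rows(out)
  })
  pieces <- dplyr::bind_rows(pieces)
  if (nrow(pieces) == 0L) {
    pieces <- tibble::tibble(id = character(), samples = list(), fs = numeric(),
                             lead_id = character(), group_id = character(),
                             label = as_quality(character()))
  }
  class(pieces) <- c("ecg_tbl", class(tibble::tibble()))
  pieces
}

#' Read a label-region manifest
#'
#' Delimited text with columns `id`, `start_s`, `end_s`, `label` (header
#' optional, comma- or whitespace-separated), as consumed by
#' [segment_labeled()].
#'
#' @param path Manifest path.
#' @return A tibble of regions.
#' @export
read_label_manifest <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("Missing or empty manifest: %s", path), class = "ecgsqa_format_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("id", first, fixed = TRUE)
  df <- utils::read.table(path, sep = sep, header = header, strip.white = TRUE,
                          col.names = if (header) NULL else c("id", "start_s", "end_s", "label"))
  tibble::as_tibble(df)
}
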