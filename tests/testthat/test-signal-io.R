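test_that("delimited text waveforms yield one record per lead", {
  path <- withr::local_tempfile(fileext = ".txt")
  mat <- matrix(rnorm(100 * 12), 100, 12)
  utils::write.table(mat, path, row.names = FALSE, col.names = FALSE)
  recs <- read_waveform(path, fs_hint = 500)
  expect_identical(nrow(recs), 12L)
  expect_identical(unique(recs$group_id), sub("\\.txt$", "", basename(path)))
  expect_equal(recs$samples[[3]], mat[, 3])
  # comma-separated with header also parses
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(mat[, 1:2]), path2, row.names = FALSE)
  expect_identical(nrow(read_waveform(path2, fs_hint = 250)), 2L)
})

test_that("text input without a sampling rate, and degenerate files, fail loudly", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 2\n3 4", path)
  expect_error(read_waveform(path), class = "ecgsqa_missing_rate_error")
  empty <- withr::local_tempfile(fileext = ".txt")
  file.create(empty)
  expect_error(read_waveform(empty, fs_hint = 500), class = "ecgsqa_format_error")
  expect_error(read_waveform(file.path(tempdir(), "nope.txt")),
               class = "ecgsqa_format_error")
})

test_that("WAV round trip preserves rate, length and amplitudes", {
  x <- sin(2 * pi * 7 * (0:4999) / 500)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 500, path, bits = 32L)
  recs <- read_waveform(path)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$fs[1], 500)
  expect_length(recs$samples[[1]], 5000L)
  expect_lt(max(abs(recs$samples[[1]] - x)), 1e-6)  # float32 quantization
  # multi-channel and 16-bit PCM
  m <- cbind(x, -x, 0.5 * x)
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(m, 250, path2, bits = 16L)
  recs2 <- read_waveform(path2)
  expect_identical(nrow(recs2), 3L)
  expect_lt(max(abs(recs2$samples[[2]] + x)), 1e-4)  # 16-bit quantization
})

test_that("resampling changes length by the rate ratio and keeps tones in place", {
  rec <- ecg_corpus(list(sin(2 * pi * 5 * (0:9999) / 1000)), fs = 1000)
  down <- ecg_resample(rec, 500)
  expect_length(down$samples[[1]], 5000L)
  expect_identical(down$fs[1], 500)
  # identity
  same <- ecg_resample(rec, 1000)
  expect_identical(same$samples[[1]], rec$samples[[1]])
  # dominant spectral peak still at 5 Hz after downsampling
  y <- down$samples[[1]]
  spec <- Mod(stats::fft(y))[1:2500]
  peak_hz <- (which.max(spec[-1])) * 500 / length(y)  # skip DC
  expect_equal(peak_hz, 5, tolerance = 0.05)
  expect_error(ecg_resample(rec, 0), class = "ecgsqa_invalid_argument")
})

test_that("down-up-down resampling returns close to the original band-limited signal", {
  rec <- make_clean_ecg(10, 500, 60, seed = 8)
  back <- ecg_resample(ecg_resample(rec, 1000), 500)
  a <- rec$samples[[1]]
  b <- back$samples[[1]]
  core <- 100:4900  # ignore filter edge effects
  expect_lt(stats::sd(a[core] - b[core]) / stats::sd(a[core]), 0.02)
})

test_that("min-max normalization maps endpoints exactly and constants to zero", {
  expect_equal(ecg_normalize(ecg_corpus(list(c(0, 5, 10)), 1))$samples[[1]],
               c(-1, 0, 1))
  expect_equal(ecg_normalize(ecg_corpus(list(c(3, 3, 3)), 1))$samples[[1]],
               c(0, 0, 0))
  expect_equal(ecg_normalize(ecg_corpus(list(c(-2, 2)), 1))$samples[[1]],
               c(-1, 1))
  # property: every non-constant record attains both -1 and 1, nothing outside
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(50) * 10^runif(1, -3, 3) + runif(1, -100, 100)
    y <- ecg_normalize(ecg_corpus(list(x), 1))$samples[[1]]
    expect_equal(range(y), c(-1, 1))
  }
})

test_that("labeled regions are cut into floor(duration/window) inherited-label windows", {
  rec <- make_clean_ecg(30, 500, 60, seed = 9)
  # a 9.9-s region is discarded entirely
  none <- segment_labeled(rec, tibble::tibble(start_s = 0, end_s = 9.9,
                                              label = "acceptable"))
  expect_identical(nrow(none), 0L)
  # a 25-s region yields floor(25/10) = 2 windows
  two <- segment_labeled(rec, tibble::tibble(start_s = 0, end_s = 25,
                                             label = "unacceptable"))
  expect_identical(nrow(two), 2L)
  expect_true(all(two$label == "unacceptable"))
  expect_identical(unique(two$group_id), rec$group_id[1])
  # windows reproduce the region prefix exactly
  expect_identical(c(two$samples[[1]], two$samples[[2]]),
                   rec$samples[[1]][1:10000])
})

test_that("segment count equals the sum of per-region floors (property)", {
  set.seed(17)
  for (i in 1:10) {
    dur <- round(runif(1, 30, 80), 2)
    rec <- ecg_corpus(list(rnorm(round(dur * 100))), fs = 100)
    cuts <- sort(runif(2, 5, dur - 5))
    regions <- tibble::tibble(
      start_s = c(0, cuts[1], cuts[2]),
      end_s = c(cuts[1], cuts[2], dur),
      label = c("acceptable", "unacceptable", "acceptable")
    )
    segs <- segment_labeled(rec, regions, window_s = 10)
    expected <- sum(floor((regions$end_s - regions$start_s) / 10))
    expect_identical(nrow(segs), as.integer(expected))
  }
})

test_that("segmentation rejects malformed regions", {
  rec <- make_clean_ecg(20, 100, 60, seed = 10)
  expect_error(segment_labeled(rec, tibble::tibble(start_s = 5, end_s = 5,
                                                   label = "acceptable")),
               class = "ecgsqa_data_error")
  expect_error(segment_labeled(rec, tibble::tibble(start_s = c(0, 8),
                                                   end_s = c(10, 18),
                                                   label = "acceptable")),
               class = "ecgsqa_data_error")
  expect_error(segment_labeled(rec, tibble::tibble(start_s = 0, end_s = 25,
                                                   label = "acceptable")),
               class = "ecgsqa_data_error")
  expect_error(segment_labeled(rec, tibble::tibble(start_s = 0, end_s = 10,
                                                   label = "acceptable"),
                               window_s = 0),
               class = "ecgsqa_invalid_argument")
})
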