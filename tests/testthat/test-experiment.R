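fast_run_config <- function(seed = 1L, ...) {
  run_config(n_train = 60, n_test = 30,
             model = tiny_model_config(seed = seed, epochs = 3L),
             seed = seed, quiet = TRUE, ...)
}

test_that("run_config validates geometry and fractions before any compute", {
  expect_s3_class(fast_run_config(), "run_config")
  # STFT/model shape mismatch is caught up front
  expect_error(run_config(fs = 300, quiet = TRUE), class = "ecgsqa_config_error")
  expect_error(run_config(train_ratios = c(0.5, 1.2)), class = "ecgsqa_config_error")
  expect_error(run_config(split = c(0.5, 0.4)), class = "ecgsqa_config_error")
  expect_error(run_config(snr_acceptable_db = -5, snr_unacceptable_db = 0),
               class = "ecgsqa_config_error")
})

test_that("the two-ratio experiment emits a defined report per train ratio", {
  res <- run_experiment(fast_run_config(seed = 41L))
  expect_named(res$reports, c("85:15", "50:50"))
  expect_identical(nrow(res$comparison), 2L)
  expect_true(all(is.finite(res$comparison$f1)))
  expect_identical(res$comparison$test_ratio, rep("50:50", 2))
  expect_identical(res$comparison$train_ratio, c("85:15", "50:50"))
})

test_that("rerunning an experiment with the same config reproduces it exactly", {
  cfg <- fast_run_config(seed = 43L)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  r1 <- run_experiment(cfg, out_dir = out1)
  r2 <- run_experiment(cfg, out_dir = out2)
  expect_identical(r1$comparison, r2$comparison)
  for (f in c("config.txt", "comparison.csv", "test_manifest.csv",
              "model_85-15.json", "model_50-50.json",
              "train_manifest_85-15.csv", "train_manifest_50-50.csv")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("a written run configuration reloads to an equivalent configuration", {
  cfg <- fast_run_config(seed = 45L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$n_train, cfg$n_train)
  expect_equal(back$train_ratios, cfg$train_ratios)
  expect_equal(back$model$conv_blocks, cfg$model$conv_blocks)
  expect_equal(back$model$learning_rate, cfg$model$learning_rate)
  expect_equal(back$stft$frame_length, cfg$stft$frame_length)
  expect_error(read_run_config(withr::local_tempfile(lines = "garbage line")),
               class = "ecgsqa_config_error")
})

test_that("predict_file returns one verdict row per detected lead", {
  # train a small model on a wide SNR gap so clean leads are confidently good
  train <- spectro_corpus(80, seed = 47, snr_gap = c(10, -10))
  parts <- split_corpus(train, c(0.85, 0.15, 0), seed = 48)
  m <- train_model(build_model(tiny_model_config(seed = 49L, epochs = 30L,
                                                 learning_rate = 1e-3)),
                   parts$train, parts$validation)

  clean <- make_clean_ecg(20, 500, 65, seed = 50)$samples[[1]]
  noisy <- add_noise(ecg_corpus(list(clean), 500),
                     noise_spec("composite", target_snr_db = -12, seed = 51))$samples[[1]]
  path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(cbind(clean, noisy), path, row.names = FALSE,
                     col.names = FALSE)
  verdict <- predict_file(m, path, fs_hint = 500)
  expect_identical(nrow(verdict), 2L)
  expect_identical(verdict$n_windows, c(2L, 2L))
  expect_identical(as.character(verdict$label[1]), "acceptable")
  expect_gt(verdict$prob_acceptable[1], 0.5)
  expect_identical(as.character(verdict$label[2]), "unacceptable")
  # per-window detail is nested
  expect_identical(nrow(verdict$windows[[1]]), 2L)

  # a recording shorter than one analysis window is rejected
  short_path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(cbind(clean[1:1000]), short_path, row.names = FALSE,
                     col.names = FALSE)
  expect_error(predict_file(m, short_path, fs_hint = 500),
               class = "ecgsqa_data_error")
})

test_that("a saved model store drives predict_file identically to the live model", {
  train <- spectro_corpus(24, seed = 53, snr_gap = c(15, -15))
  parts <- split_corpus(train, c(0.75, 0.25, 0), seed = 54)
  m <- train_model(build_model(tiny_model_config(seed = 55L, epochs = 2L)),
                   parts$train, parts$validation)
  store <- withr::local_tempfile(fileext = ".json")
  save_model(m, store)
  wave <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(cbind(make_clean_ecg(10, 500, 70, seed = 56)$samples[[1]]),
                     wave, row.names = FALSE, col.names = FALSE)
  v_live <- predict_file(m, wave, fs_hint = 500)
  v_store <- predict_file(store, wave, fs_hint = 500)
  expect_identical(v_live$prob_acceptable, v_store$prob_acceptable)
})

test_that("the command-line interface runs its simulate subcommand end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "ecgsqa.R", package = "ecgsqa")
  expect_true(nzchar(cli))
  out <- withr::local_tempdir()
  res <- system2("Rscript", c(cli, "simulate", "--out", out, "--n", "4",
                              "--seed", "3", "--quiet"),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(out, "labels.csv")))
  recs <- list.files(out, pattern = "^synth.*\\.txt$")
  expect_identical(length(recs), 4L)
  manifest <- read.csv(file.path(out, "labels.csv"))
  expect_identical(nrow(manifest), 4L)
  expect_true(all(c("id", "label", "group_id") %in% names(manifest)))
})
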