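# End-to-end workflow: simulate -> prepare -> train -> evaluate, including
# the class-ratio comparison experiment (train at several acceptable:
# unacceptable ratios, evaluate every model on one shared balanced test set).

#' Workflow configuration
#'
#' Bundles every knob of an end-to-end run: synthetic-corpus sizes and SNR
#' levels, STFT parameters, model hyperparameters, split fractions, ratios
#' to compare, sampling rate, seed and logging. Validated up front, before
#' any compute.
#'
#' @param n_train Training-corpus size per ratio configuration.
#' @param n_test Shared test-corpus size (balanced 50:50).
#' @param train_ratios Acceptable fractions to train at (one model each).
#' @param test_ratio Acceptable fraction of the shared test corpus.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds.
#' @param snr_acceptable_db,snr_unacceptable_db SNR band edges (dB) for the
#'   synthetic classes.
#' @param split Train/validation fractions applied within each training
#'   corpus (test fraction is 0: the test set is independent).
#' @param stft An [stft_params()] object.
#' @param model A [model_config()] object.
#' @param seed Master seed; stage seeds are derived from it.
#' @param quiet Suppress progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(n_train = 2000L, n_test = 400L,
                       train_ratios = c(0.85, 0.5), test_ratio = 0.5,
                       fs = 500, window_s = 10,
                       snr_acceptable_db = 10, snr_unacceptable_db = -10,
                       split = c(0.9, 0.1),
                       stft = stft_params(), model = model_config(),
                       seed = 1L, quiet = FALSE) {
  check_scalar_number(n_train, "n_train", positive = TRUE)
  check_scalar_number(n_test, "n_test", positive = TRUE)
  check_scalar_number(fs, "fs", positive = TRUE)
  check_scalar_number(window_s, "window_s", positive = TRUE)
  if (length(train_ratios) < 1L || any(train_ratios <= 0 | train_ratios >= 1)) {
    abort("`train_ratios` must lie strictly between 0 and 1.",
          class = "ecgsqa_config_error")
  }
  if (test_ratio <= 0 || test_ratio >= 1) {
    abort("`test_ratio` must lie strictly between 0 and 1.",
          class = "ecgsqa_config_error")
  }
  if (length(split) != 2L || any(split <= 0) || abs(sum(split) - 1) > 1e-8) {
    abort("`split` must be two positive train/validation fractions summing to 1.",
          class = "ecgsqa_config_error")
  }
  if (snr_acceptable_db <= snr_unacceptable_db) {
    abort("`snr_acceptable_db` must exceed `snr_unacceptable_db`.",
          class = "ecgsqa_config_error")
  }
  if (!inherits(stft, "stft_params")) {
    abort("`stft` must come from stft_params().", class = "ecgsqa_config_error")
  }
  if (!inherits(model, "model_config")) {
    abort("`model` must come from model_config().", class = "ecgsqa_config_error")
  }
  frames <- (round(window_s * fs) - stft$frame_length) %/% stft$frame_step + 1L
  bins <- stft$frame_length %/% 2L + 1L
  if (!identical(as.integer(c(frames, bins)), model$input_shape)) {
    abort(sprintf(
      "STFT of a %g-s, %g-Hz segment gives shape (%d, %d) but the model expects (%d, %d).",
      window_s, fs, frames, bins, model$input_shape[1], model$input_shape[2]),
      class = "ecgsqa_config_error")
  }
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 train_ratios = train_ratios, test_ratio = test_ratio,
                 fs = fs, window_s = window_s,
                 snr_acceptable_db = snr_acceptable_db,
                 snr_unacceptable_db = snr_unacceptable_db,
                 split = split, stft = stft, model = model,
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "run_config")
}

log_stage <- function(config, stage, fmt, ...) {
  if (!isTRUE(config$quiet)) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

ratio_label <- function(r) sprintf("%.0f:%.0f", 100 * r, 100 * (1 - r))

#' Run the class-ratio comparison experiment
#'
#' Reproduces, on synthetic data, the experiment design in which one
#' classifier is trained on a skewed (e.g. 85:15) corpus and another on a
#' balanced (50:50) corpus, and both are evaluated on the *same* balanced
#' test set, isolating the effect of training class representation on the
#' reported metrics.
#'
#' For each ratio the training corpus is drawn by [build_ratio_corpus()]
#' from one shared pool pair, split train/validation, converted to
#' spectrograms, and used to train a fresh CNN-LSTM; every model is then
#' evaluated on the shared test corpus. All randomness derives from
#' `config$seed`, so reruns are bit-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the resolved
#'   configuration, corpus manifests, model stores and reports are written
#'   there (enough to re-run the experiment).
#' @return List with `reports` (one `ecg_eval` per train ratio, named by
#'   ratio label) and `comparison` (one-row-per-ratio tibble).
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) {
    abort("`config` must come from run_config().", class = "ecgsqa_config_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (!is.null(out_dir)) write_run_config(config, file.path(out_dir, "config.txt"))

  # Pool sizes covering the most demanding ratio on each side.
  need_acc <- max(vapply(config$train_ratios,
                         function(r) round(config$n_train * r), numeric(1)))
  need_una <- max(vapply(config$train_ratios,
                         function(r) config$n_train - round(config$n_train * r),
                         numeric(1)))
  n_pool <- need_acc + need_una
  log_stage(config, "simulate", "pool of %d records (%d acceptable, %d unacceptable)",
            n_pool, need_acc, need_una)
  pool <- make_labeled_corpus(n_pool, need_acc / n_pool, fs = config$fs,
                              snr_acceptable_db = config$snr_acceptable_db,
                              snr_unacceptable_db = config$snr_unacceptable_db,
                              seed = config$seed, duration_s = config$window_s)
  pool_acc <- pool[pool$label == "acceptable", ]
  pool_una <- pool[pool$label == "unacceptable", ]

  log_stage(config, "simulate", "shared test corpus of %d records (%s)",
            config$n_test, ratio_label(config$test_ratio))
  test <- make_labeled_corpus(config$n_test, config$test_ratio, fs = config$fs,
                              snr_acceptable_db = config$snr_acceptable_db,
                              snr_unacceptable_db = config$snr_unacceptable_db,
                              seed = config$seed + 7919L,
                              duration_s = config$window_s)
  test$id <- paste0("test_", test$id)
  test$group_id <- paste0("test_", test$group_id)
  log_stage(config, "prepare", "computing test spectrograms")
  test_sp <- ecg_spectrograms(test, config$stft, config$fs, config$window_s)

  reports <- list()
  for (k in seq_along(config$train_ratios)) {
    r <- config$train_ratios[k]
    lab <- ratio_label(r)
    stage_seed <- config$seed + 101L * k
    log_stage(config, "prepare", "train corpus at ratio %s", lab)
    corp <- build_ratio_corpus(pool_acc, pool_una, r, seed = stage_seed)
    parts <- split_corpus(corp, c(config$split, 0), seed = stage_seed + 1L)
    train_sp <- ecg_spectrograms(parts$train, config$stft, config$fs, config$window_s)
    val_sp <- ecg_spectrograms(parts$validation, config$stft, config$fs, config$window_s)

    mcfg <- config$model
    mcfg$seed <- stage_seed + 2L
    log_stage(config, "train", "ratio %s: %d train / %d validation segments",
              lab, nrow(train_sp), nrow(val_sp))
    model <- build_model(mcfg)
    model <- train_model(model, train_sp, val_sp)
    log_stage(config, "train", "ratio %s: stopped after %d epochs (best %d)",
              lab, max(model$history$epoch), model$best_epoch)

    log_stage(config, "evaluate", "ratio %s on shared test set", lab)
    rep_k <- evaluate_model(model, test_sp, train_ratio = lab)
    reports[[lab]] <- rep_k

    if (!is.null(out_dir)) {
      tag <- gsub(":", "-", lab)
      save_model(model, file.path(out_dir, sprintf("model_%s.json", tag)))
      assigned <- dplyr::bind_rows(
        dplyr::mutate(parts$train, partition = "train"),
        dplyr::mutate(parts$validation, partition = "validation")
      )
      write_corpus_manifest(assigned, file.path(out_dir, sprintf("train_manifest_%s.csv", tag)))
    }
  }
  comparison <- dplyr::bind_rows(lapply(reports, glance))
  if (!is.null(out_dir)) {
    write_corpus_manifest(test, file.path(out_dir, "test_manifest.csv"))
    report_table(reports, file.path(out_dir, "comparison.csv"))
  }
  log_stage(config, "evaluate", "done (%d reports)", length(reports))
  list(reports = reports, comparison = comparison)
}

#' Classify every lead of a waveform file
#'
#' Reads a delimited-text or WAV waveform, and for each detected lead:
#' resamples to the model's rate, cuts the lead into consecutive
#' non-overlapping analysis windows (the tail shorter than one window is
#' discarded), scores each window with the classifier, and reports the
#' majority label per lead (ties are conservatively unacceptable).
#'
#' @param model A trained `ecg_model`, or a path to a model store.
#' @param waveform_path Waveform file path.
#' @param fs_hint Sampling rate for text input.
#' @param fs,window_s Rate (Hz) and window length (s) the model was trained
#'   at.
#' @param stft [stft_params()] used at training time.
#' @param threshold Decision threshold per window.
#' @return A tibble with one row per lead: `lead_id`, `label`,
#'   `prob_acceptable` (mean window probability), `n_windows`,
#'   `n_acceptable`, and a nested `windows` tibble of per-window detail.
#' @export
predict_file <- function(model, waveform_path, fs_hint = NULL, fs = 500,
                         window_s = 10, stft = stft_params(), threshold = 0.5) {
  if (is.character(model)) model <- load_model(model)
  leads <- read_waveform(waveform_path, fs_hint = fs_hint)
  leads <- ecg_resample(leads, fs)
  win_n <- as.integer(round(window_s * fs))
  if (any(lengths(leads$samples) < win_n)) {
    abort(sprintf("Recording shorter than one %g-s analysis window.", window_s),
          class = "ecgsqa_data_error")
  }
  out <- lapply(seq_len(nrow(leads)), function(i) {
    x <- leads$samples[[i]]
    n_win <- as.integer(length(x) %/% win_n)
    wins <- ecg_corpus(
      lapply(seq_len(n_win), function(w) x[(w - 1L) * win_n + seq_len(win_n)]),
      fs = fs, id = sprintf("%s_w%d", leads$id[i], seq_len(n_win)),
      lead_id = leads$lead_id[i], group_id = leads$group_id[i]
    )
    wins <- ecg_spectrograms(wins, stft, fs, window_s)
    pred <- predict(model, wins, threshold = threshold)
    n_acc <- sum(pred$.pred_label == "acceptable")
    tibble::tibble(
      lead_id = leads$lead_id[i],
      label = as_quality(if (n_acc > n_win / 2) "acceptable" else "unacceptable"),
      prob_acceptable = mean(pred$.prob_acceptable),
      n_windows = n_win,
      n_acceptable = n_acc,
      windows = list(tibble::as_tibble(pred[c("id", ".prob_acceptable", ".pred_label")]))
    )
  })
  dplyr::bind_rows(out)
}

#' Write / read a workflow configuration as plain text
#'
#' Key-value text (`key = value`), nested STFT/model fields prefixed
#' `stft.` / `model.`; every run writes its resolved configuration next to
#' its outputs so it can be reproduced exactly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` invisibly; `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  lines <- c(
    sprintf("n_train = %s", fmt(config$n_train)),
    sprintf("n_test = %s", fmt(config$n_test)),
    sprintf("train_ratios = %s", fmt(config$train_ratios)),
    sprintf("test_ratio = %s", fmt(config$test_ratio)),
    sprintf("fs = %s", fmt(config$fs)),
    sprintf("window_s = %s", fmt(config$window_s)),
    sprintf("snr_acceptable_db = %s", fmt(config$snr_acceptable_db)),
    sprintf("snr_unacceptable_db = %s", fmt(config$snr_unacceptable_db)),
    sprintf("split = %s", fmt(config$split)),
    sprintf("seed = %s", fmt(config$seed)),
    sprintf("quiet = %s", fmt(config$quiet)),
    sprintf("stft.frame_length = %s", fmt(config$stft$frame_length)),
    sprintf("stft.frame_step = %s", fmt(config$stft$frame_step)),
    sprintf("model.conv_blocks = %s",
            paste(vapply(config$model$conv_blocks,
                         function(b) paste(b, collapse = "x"), character(1)),
                  collapse = " ")),
    sprintf("model.pool_size = %s", fmt(config$model$pool_size)),
    sprintf("model.dropout_rate = %s", fmt(config$model$dropout_rate)),
    sprintf("model.dense_units = %s", fmt(config$model$dense_units)),
    sprintf("model.lstm_units = %s", fmt(config$model$lstm_units)),
    sprintf("model.head_units = %s", fmt(config$model$head_units)),
    sprintf("model.output_units = %s", fmt(config$model$output_units)),
    sprintf("model.learning_rate = %s", format(config$model$learning_rate, digits = 17)),
    sprintf("model.loss = %s", config$model$loss),
    sprintf("model.epochs = %s", fmt(config$model$epochs)),
    sprintf("model.batch_size = %s", fmt(config$model$batch_size)),
    sprintf("model.patience = %s", fmt(config$model$patience))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "ecgsqa_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed config line: %s", lines[bad][1]),
          class = "ecgsqa_config_error")
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  names(vals) <- keys
  num <- function(key, default) {
    if (!key %in% keys) return(default)
    as.numeric(strsplit(vals[[key]], "\\s+")[[1]])
  }
  chr <- function(key, default) if (key %in% keys) vals[[key]] else default
  conv <- chr("model.conv_blocks", NULL)
  conv_blocks <- if (is.null(conv)) {
    list(c(64L, 3L), c(128L, 3L))
  } else {
    lapply(strsplit(conv, "\\s+")[[1]],
           function(s) as.integer(strsplit(s, "x", fixed = TRUE)[[1]]))
  }
  fs <- num("fs", 500)
  window_s <- num("window_s", 10)
  stft <- stft_params(num("stft.frame_length", 256), num("stft.frame_step", 128))
  frames <- (round(window_s * fs) - stft$frame_length) %/% stft$frame_step + 1L
  model <- model_config(
    input_shape = c(frames, stft$frame_length %/% 2L + 1L),
    conv_blocks = conv_blocks,
    pool_size = num("model.pool_size", 2),
    dropout_rate = num("model.dropout_rate", 0.3),
    dense_units = num("model.dense_units", 64),
    lstm_units = num("model.lstm_units", 64),
    head_units = num("model.head_units", 32),
    output_units = num("model.output_units", 2),
    learning_rate = num("model.learning_rate", 1e-4),
    loss = chr("model.loss", "sparse_categorical_cross_entropy"),
    epochs = num("model.epochs", 50),
    batch_size = num("model.batch_size", 32),
    patience = num("model.patience", 10),
    seed = num("seed", 1)
  )
  run_config(
    n_train = num("n_train", 2000), n_test = num("n_test", 400),
    train_ratios = num("train_ratios", c(0.85, 0.5)),
    test_ratio = num("test_ratio", 0.5),
    fs = fs, window_s = window_s,
    snr_acceptable_db = num("snr_acceptable_db", 10),
    snr_unacceptable_db = num("snr_unacceptable_db", -10),
    split = num("split", c(0.9, 0.1)),
    stft = stft, model = model,
    seed = num("seed", 1),
    quiet = identical(tolower(chr("quiet", "false")), "true")
  )
}
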