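# User-facing CNN-LSTM quality classifier.

#' CNN-LSTM model configuration
#'
#' Hyperparameters of the quality classifier. The topology is: input
#' (frames, bins) -> feature-wise normalization -> repeated
#' \[1-D convolution -> max-pool -> dropout\] blocks -> time-distributed dense
#' -> LSTM over the remaining frames -> dropout -> dense -> output. The
#' default output is a 2-unit softmax trained with sparse categorical
#' cross-entropy; `loss = "binary_cross_entropy"` switches to a 1-unit
#' sigmoid output.
#'
#' @param input_shape Integer pair (time frames, frequency bins); (38, 129)
#'   for 10-s, 500-Hz segments under the default STFT parameters.
#' @param conv_blocks List of `c(filters, kernel)` pairs, one per
#'   convolution block (odd kernels, "same" padding).
#' @param pool_size Max-pool width/stride along the time axis.
#' @param dropout_rate Dropout fraction in `[0, 1)` (applied after each pool
#'   and after the LSTM, training only).
#' @param dense_units Width of the time-distributed dense layer feeding the
#'   LSTM.
#' @param lstm_units LSTM hidden-state size.
#' @param head_units Width of the post-LSTM dense layer.
#' @param output_units 2 (softmax) or 1 (sigmoid).
#' @param learning_rate Adam step size (default 1e-4).
#' @param loss `"sparse_categorical_cross_entropy"` (needs 2 output units)
#'   or `"binary_cross_entropy"` (needs 1).
#' @param epochs,batch_size Training schedule.
#' @param patience Early-stopping patience on validation loss (epochs);
#'   `Inf` disables early stopping.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(input_shape = c(38L, 129L),
                         conv_blocks = list(c(64L, 3L), c(128L, 3L)),
                         pool_size = 2L,
                         dropout_rate = 0.3,
                         dense_units = 64L,
                         lstm_units = 64L,
                         head_units = 32L,
                         output_units = 2L,
                         learning_rate = 1e-4,
                         loss = c("sparse_categorical_cross_entropy",
                                  "binary_cross_entropy"),
                         epochs = 50L,
                         batch_size = 32L,
                         patience = 10,
                         seed = 1L) {
  loss <- match.arg(loss)
  check_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).", class = "ecgsqa_config_error")
  }
  if (!output_units %in% c(1L, 2L)) {
    abort("`output_units` must be 1 or 2.", class = "ecgsqa_config_error")
  }
  if (loss == "sparse_categorical_cross_entropy" && output_units != 2L) {
    abort("Sparse categorical cross-entropy needs 2 output units.",
          class = "ecgsqa_config_error")
  }
  if (loss == "binary_cross_entropy" && output_units != 1L) {
    abort("Binary cross-entropy needs 1 output unit.", class = "ecgsqa_config_error")
  }
  if (length(input_shape) != 2L || any(input_shape < 2)) {
    abort("`input_shape` must be two integers (frames, bins).",
          class = "ecgsqa_config_error")
  }
  for (cb in conv_blocks) {
    if (length(cb) != 2L || cb[1] < 1 || cb[2] < 1 || cb[2] %% 2L != 1L) {
      abort("Each conv block must be c(filters, odd kernel).",
            class = "ecgsqa_config_error")
    }
  }
  # Time frames surviving the conv/pool stack must leave the LSTM >= 1 step.
  tn <- input_shape[1]
  for (cb in conv_blocks) tn <- tn %/% pool_size
  if (tn < 1L) {
    abort("Conv/pool stack consumes all time frames; reduce pooling.",
          class = "ecgsqa_config_error")
  }
  structure(list(
    input_shape = as.integer(input_shape),
    conv_blocks = lapply(conv_blocks, as.integer),
    pool_size = as.integer(pool_size),
    dropout_rate = dropout_rate,
    dense_units = as.integer(dense_units),
    lstm_units = as.integer(lstm_units),
    head_units = as.integer(head_units),
    output_units = as.integer(output_units),
    learning_rate = learning_rate,
    loss = loss,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    patience = patience,
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Build an untrained CNN-LSTM quality classifier
#'
#' Initializes all layer weights (Glorot uniform, forget-gate bias 1) from
#' `config$seed`. The feature-wise normalization layer is adapted to the
#' training data during [train_model()].
#'
#' @param config A [model_config()].
#' @return An `ecg_model` object (weights, config, empty history).
#' @export
build_model <- function(config = model_config()) {
  if (!inherits(config, "model_config")) {
    abort("`config` must be created with model_config().", class = "ecgsqa_config_error")
  }
  par <- with_seed(config$seed, nn_init_params(config))
  structure(list(par = par, config = config,
                 history = tibble::tibble(epoch = integer(), loss = numeric(),
                                          accuracy = numeric(),
                                          val_loss = numeric(),
                                          val_accuracy = numeric()),
                 trained = FALSE, version = model_store_version()),
            class = "ecg_model")
}

model_store_version <- function() "ecgsqa-model-1"

#' @export
print.ecg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ecg_model> CNN-LSTM quality classifier (%s)\n",
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  input (%d, %d) | conv %s | dense %d | lstm %d | head %d | out %d (%s)\n",
              cfg$input_shape[1], cfg$input_shape[2],
              paste(vapply(cfg$conv_blocks, function(b) sprintf("%dx k%d", b[1], b[2]),
                           character(1)), collapse = " -> "),
              cfg$dense_units, cfg$lstm_units, cfg$head_units, cfg$output_units,
              cfg$loss))
  cat(sprintf("  trainable parameters: %d\n", nn_param_count(x$par)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  last epoch %d: loss %.4f acc %.4f val_loss %.4f val_acc %.4f\n",
                last$epoch, last$loss, last$accuracy, last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

# Stack the spectrogram list-column of a corpus into a time-major matrix
# (B*T) x F plus the 0/1 label vector.
corpus_tensors <- function(data, config, require_label = TRUE, arg = "data") {
  data <- as_ecg_tbl(data, require_label = require_label, arg = arg)
  if (!"spectrogram" %in% names(data)) {
    abort(sprintf("`%s` lacks a `spectrogram` column; run ecg_spectrograms() first.", arg),
          class = "ecgsqa_data_error")
  }
  shp <- config$input_shape
  for (i in seq_len(nrow(data))) {
    d <- dim(data$spectrogram[[i]])
    if (!identical(as.integer(d), shp)) {
      abort(sprintf("Record `%s` has spectrogram shape (%d, %d); model expects (%d, %d).",
                    data$id[i], d[1], d[2], shp[1], shp[2]),
            class = "ecgsqa_data_error")
    }
  }
  B <- nrow(data)
  Tn <- shp[1]
  X <- matrix(0, B * Tn, shp[2])
  for (i in seq_len(B)) {
    X[seq.int(i, by = B, length.out = Tn), ] <- data$spectrogram[[i]]
  }
  y <- if (require_label) as.integer(data$label) - 1L else NULL
  list(X = X, y = y, B = B)
}

#' Train the quality classifier
#'
#' Adam optimization (default learning rate 1e-4) of the configured loss for
#' up to `config$epochs` epochs with minibatches of `config$batch_size`,
#' recording training and validation loss/accuracy per epoch. Early stopping
#' monitors validation loss with `config$patience`; the best-validation
#' weights are restored. The normalization layer is adapted (per-frequency
#' mean/sd) on the training corpus before optimization. Training is
#' deterministic for a fixed seed and thread configuration (single-threaded
#' BLAS; with a multi-threaded BLAS, reductions may reorder and results can
#' differ in the last bits).
#'
#' @param model An `ecg_model` from [build_model()].
#' @param train,val Labeled corpora carrying a `spectrogram` column (see
#'   [ecg_spectrograms()]).
#' @param epochs Optional override of `config$epochs`.
#' @return The trained `ecg_model` with a filled `history` tibble.
#' @export
train_model <- function(model, train, val, epochs = NULL) {
  if (!inherits(model, "ecg_model")) {
    abort("`model` must come from build_model().", class = "ecgsqa_config_error")
  }
  config <- model$config
  n_epochs <- as.integer(epochs %||% config$epochs)
  tr <- corpus_tensors(train, config, arg = "train")
  va <- corpus_tensors(val, config, arg = "val")

  par <- model$par
  # Adapt the normalization layer: per-frequency-bin mean/sd over all
  # training frames.
  par$norm$mu <- colMeans(tr$X)
  sd_ <- sqrt(pmax(colMeans(tr$X^2) - par$norm$mu^2, 0))
  par$norm$sd <- pmax(sd_, 1e-6)

  if (n_epochs == 0L) {
    model$par <- par
    model$trained <- TRUE
    return(model)
  }

  state <- adam_state(par)
  hist <- vector("list", n_epochs)
  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L

  with_seed(config$seed, {
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(tr$B)
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, tr$B, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, tr$B)]
        nb <- length(take)
        rows <- as.vector(outer(take, (seq_len(config$input_shape[1]) - 1L) * tr$B, `+`))
        Xb <- tr$X[rows, , drop = FALSE]
        yb <- tr$y[take]
        fwd <- nn_forward(par, Xb, nb, config, training = TRUE, y = yb)
        if (!is.finite(fwd$loss)) {
          abort(sprintf("Training diverged (non-finite loss at epoch %d).", ep),
                class = "ecgsqa_runtime_error")
        }
        grads <- nn_backward(par, fwd, yb, config)
        r <- adam_update(par, grads, state, config$learning_rate)
        par <- r$par
        state <- r$state
        ep_loss <- ep_loss + fwd$loss * nb
        ep_correct <- ep_correct + sum((fwd$p_acceptable > 0.5) == (yb == 1L))
      }
      vfwd <- nn_forward(par, va$X, va$B, config, training = FALSE, y = va$y)
      hist[[ep]] <- tibble::tibble(
        epoch = ep,
        loss = ep_loss / tr$B,
        accuracy = ep_correct / tr$B,
        val_loss = vfwd$loss,
        val_accuracy = mean((vfwd$p_acceptable > 0.5) == (va$y == 1L))
      )
      if (vfwd$loss < best$loss - 1e-9) {
        best <- list(loss = vfwd$loss, par = par, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (is.finite(config$patience) && wait >= config$patience) break
      }
    }
  })

  model$par <- best$par
  model$history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model
}

#' Predict quality labels for spectrograms
#'
#' Returns the probability of the acceptable class per segment; a segment is
#' labeled acceptable iff `p > threshold` (a tie at the threshold is
#' conservatively unacceptable).
#'
#' @param object A (trained) `ecg_model`.
#' @param new_data An ECG corpus tibble with a `spectrogram` column, or a
#'   list of spectrogram matrices.
#' @param threshold Decision threshold on the acceptable-class probability.
#' @param ... Unused.
#' @return `new_data` with `.prob_acceptable` and `.pred_label` columns (a
#'   tibble with `id`, `.prob_acceptable`, `.pred_label` when a bare list of
#'   matrices was supplied). Zero rows in, zero rows out.
#' @export
predict.ecg_model <- function(object, new_data, threshold = 0.5, ...) {
  bare <- !is.data.frame(new_data)
  if (bare) {
    if (length(new_data) == 0L) {
      return(tibble::tibble(id = character(), .prob_acceptable = numeric(),
                            .pred_label = as_quality(character())))
    }
    new_data <- tibble::tibble(
      id = sprintf("input%d", seq_along(new_data)),
      samples = list(0), fs = NA_real_, spectrogram = new_data
    )
    new_data$samples <- lapply(new_data$spectrogram, function(m) numeric(1))
    new_data$fs <- 1
    new_data <- as_ecg_tbl(new_data)
  }
  tensors <- corpus_tensors(new_data, object$config, require_label = FALSE,
                            arg = "new_data")
  fwd <- nn_forward(object$par, tensors$X, tensors$B, object$config,
                    training = FALSE)
  out <- new_data
  out$.prob_acceptable <- fwd$p_acceptable
  out$.pred_label <- as_quality(ifelse(fwd$p_acceptable > threshold,
                                       "acceptable", "unacceptable"))
  if (bare) out <- tibble::as_tibble(out[c("id", ".prob_acceptable", ".pred_label")])
  out
}

# ---- persistence ----------------------------------------------------------

flatten_params <- function(par) {
  rapply(par, function(x) list(dim = dim(x) %||% length(x), data = as.numeric(x)),
         how = "list")
}

unflatten_params <- function(spec) {
  rebuild <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      d <- unlist(x$dim)
      v <- unlist(x$data)
      if (length(d) == 2L) matrix(v, d[1], d[2]) else v
    } else {
      lapply(x, rebuild)
    }
  }
  rebuild(spec)
}

#' Save / load a trained model
#'
#' Single-file JSON archive holding a mandatory version field, the full
#' configuration, the normalization statistics, every weight matrix at full
#' double precision, and the training history. The round trip is lossless:
#' reloaded models produce bitwise-identical predictions, and saving the
#' same model twice yields identical bytes.
#'
#' @param model A trained `ecg_model`.
#' @param path File path for the model store.
#' @return `save_model()`: `path` invisibly; `load_model()`: the restored
#'   `ecg_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ecg_model")) {
    abort("`model` must be an ecg_model.", class = "ecgsqa_config_error")
  }
  cfg <- unclass(model$config)
  cfg$patience <- if (is.finite(cfg$patience)) cfg$patience else -1
  payload <- list(
    version = model$version,
    config = cfg,
    trained = model$trained,
    best_epoch = model$best_epoch %||% NA_integer_,
    history = as.list(model$history),
    par = flatten_params(model$par)
  )
  # I(17) significant digits: lossless text round trip for IEEE doubles
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model store not found: %s", path), class = "ecgsqa_load_error")
  }
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                         simplifyDataFrame = FALSE),
                      error = function(e) {
                        abort(sprintf("Corrupt model store %s: %s", path,
                                      conditionMessage(e)),
                              class = "ecgsqa_load_error")
                      })
  if (is.null(payload$version) || !identical(payload$version, model_store_version())) {
    abort(sprintf("Model store version `%s` does not match supported `%s`.",
                  payload$version %||% "<missing>", model_store_version()),
          class = "ecgsqa_load_error")
  }
  cfg <- payload$config
  config <- model_config(
    input_shape = cfg$input_shape,
    conv_blocks = if (is.matrix(cfg$conv_blocks)) {
      lapply(seq_len(nrow(cfg$conv_blocks)), function(i) cfg$conv_blocks[i, ])
    } else cfg$conv_blocks,
    pool_size = cfg$pool_size, dropout_rate = cfg$dropout_rate,
    dense_units = cfg$dense_units, lstm_units = cfg$lstm_units,
    head_units = cfg$head_units, output_units = cfg$output_units,
    learning_rate = cfg$learning_rate, loss = cfg$loss, epochs = cfg$epochs,
    batch_size = cfg$batch_size,
    patience = if (cfg$patience < 0) Inf else cfg$patience,
    seed = cfg$seed
  )
  structure(list(par = unflatten_params(payload$par), config = config,
                 history = tibble::as_tibble(payload$history),
                 trained = isTRUE(payload$trained),
                 best_epoch = payload$best_epoch,
                 version = payload$version),
            class = "ecg_model")
}

# ---- broom-style methods --------------------------------------------------

#' Tidy the training history of a model
#'
#' @param x An `ecg_model`.
#' @param ... Unused.
#' @return A tibble with one row per (epoch, metric): columns `epoch`,
#'   `metric`, `value`.
#' @method tidy ecg_model
#' @export
tidy.ecg_model <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a model
#'
#' @param x An `ecg_model`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, best epoch, final
#'   training/validation loss and accuracy.
#' @method glance ecg_model
#' @export
glance.ecg_model <- function(x, ...) {
  h <- x$history
  last <- if (nrow(h)) h[nrow(h), ] else
    tibble::tibble(epoch = 0L, loss = NA_real_, accuracy = NA_real_,
                   val_loss = NA_real_, val_accuracy = NA_real_)
  tibble::tibble(
    n_parameters = nn_param_count(x$par),
    epochs_run = last$epoch,
    best_epoch = x$best_epoch %||% NA_integer_,
    loss = last$loss, accuracy = last$accuracy,
    val_loss = last$val_loss, val_accuracy = last$val_accuracy
  )
}

#' Plot the training history
#'
#' @param object An `ecg_model` with a non-empty history.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy curves over epochs.
#' @method autoplot ecg_model
#' @export
autoplot.ecg_model <- function(object, ...) {
  df <- tidy(object)
  df$set <- ifelse(grepl("^val_", df$metric), "validation", "training")
  df$metric <- sub("^val_", "", df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
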