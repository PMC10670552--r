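# The network's analytic gradients are the heart of the classifier; they are
# verified here against central finite differences on a small topology.

test_that("backprop gradients match finite differences for every layer", {
  cfg <- model_config(input_shape = c(8L, 5L),
                      conv_blocks = list(c(4L, 3L), c(6L, 3L)),
                      pool_size = 2L, dropout_rate = 0, dense_units = 4L,
                      lstm_units = 3L, head_units = 3L, output_units = 2L,
                      seed = 42L)
  m <- build_model(cfg)
  set.seed(9)
  B <- 5L
  X <- matrix(rnorm(B * 8L * 5L), B * 8L, 5L)
  y <- sample(0:1, B, replace = TRUE)
  par <- m$par
  fwd <- ecgsqa:::nn_forward(par, X, B, cfg, training = FALSE, y = y)
  gr <- ecgsqa:::nn_backward(par, fwd, y, cfg)

  num_grad <- function(get, set) {
    w <- get(par)
    g <- numeric(length(w))
    eps <- 1e-6
    for (i in seq_along(w)) {
      up <- set(par, replace(w, i, w[i] + eps))
      dn <- set(par, replace(w, i, w[i] - eps))
      g[i] <- (ecgsqa:::nn_forward(up, X, B, cfg, FALSE, y)$loss -
                 ecgsqa:::nn_forward(dn, X, B, cfg, FALSE, y)$loss) / (2 * eps)
    }
    g
  }
  cases <- list(
    conv1_W = list(get = function(p) p$conv[[1]]$W,
                   set = function(p, v) { p$conv[[1]]$W[] <- v; p },
                   grad = gr$conv[[1]]$W),
    conv2_W = list(get = function(p) p$conv[[2]]$W,
                   set = function(p, v) { p$conv[[2]]$W[] <- v; p },
                   grad = gr$conv[[2]]$W),
    dense_W = list(get = function(p) p$dense$W,
                   set = function(p, v) { p$dense$W[] <- v; p },
                   grad = gr$dense$W),
    lstm_Wx = list(get = function(p) p$lstm$Wx,
                   set = function(p, v) { p$lstm$Wx[] <- v; p },
                   grad = gr$lstm$Wx),
    lstm_Wh = list(get = function(p) p$lstm$Wh,
                   set = function(p, v) { p$lstm$Wh[] <- v; p },
                   grad = gr$lstm$Wh),
    head_W = list(get = function(p) p$head$W,
                  set = function(p, v) { p$head$W[] <- v; p },
                  grad = gr$head$W),
    out_W = list(get = function(p) p$out$W,
                 set = function(p, v) { p$out$W[] <- v; p },
                 grad = gr$out$W)
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    ng <- num_grad(cs$get, cs$set)
    rel <- max(abs(ng - as.numeric(cs$grad))) / max(1e-8, max(abs(ng)))
    expect_lt(rel, 1e-5)
  }
})

test_that("model configuration enforces its invariants", {
  expect_error(model_config(dropout_rate = 1.0), class = "ecgsqa_config_error")
  expect_s3_class(model_config(dropout_rate = 0.99), "model_config")
  expect_error(model_config(output_units = 3L), class = "ecgsqa_config_error")
  expect_error(model_config(output_units = 1L), class = "ecgsqa_config_error")
  expect_s3_class(model_config(output_units = 1L, loss = "binary_cross_entropy"),
                  "model_config")
  expect_error(model_config(learning_rate = 0), class = "ecgsqa_invalid_argument")
  expect_error(model_config(conv_blocks = list(c(8L, 4L))),
               class = "ecgsqa_config_error")
})

test_that("softmax outputs are normalized probabilities for every segment", {
  cfg <- tiny_model_config(seed = 2L)
  m <- build_model(cfg)
  corp <- spectro_corpus(8, seed = 3)
  tensors <- ecgsqa:::corpus_tensors(corp, cfg)
  fwd <- ecgsqa:::nn_forward(m$par, tensors$X, tensors$B, cfg)
  expect_true(all(fwd$prob >= 0 & fwd$prob <= 1))
  expect_equal(rowSums(fwd$prob), rep(1, tensors$B))
})

test_that("zero-epoch training adapts normalization but leaves weights at init", {
  corp <- spectro_corpus(10, seed = 4)
  m0 <- build_model(tiny_model_config(seed = 5L))
  m <- train_model(m0, corp, corp, epochs = 0L)
  expect_true(m$trained)
  expect_identical(nrow(m$history), 0L)
  expect_identical(m$par$out$W, m0$par$out$W)
  p <- predict(m, corp)
  expect_true(all(p$.prob_acceptable >= 0 & p$.prob_acceptable <= 1))
})

test_that("short training on separable data runs, records history, and stays finite", {
  corp <- spectro_corpus(40, seed = 6, snr_gap = c(15, -15))
  parts <- split_corpus(corp, c(0.8, 0.2, 0), seed = 7)
  m <- train_model(build_model(tiny_model_config(seed = 8L)),
                   parts$train, parts$validation)
  expect_identical(nrow(m$history), 4L)
  expect_true(all(is.finite(m$history$loss)))
  expect_true(all(is.finite(m$history$val_loss)))
  expect_gt(m$history$accuracy[4], m$history$accuracy[1] - 0.05)
})

test_that("training is reproducible: same seed and data give identical history", {
  corp <- spectro_corpus(20, seed = 9)
  parts <- split_corpus(corp, c(0.8, 0.2, 0), seed = 10)
  cfg <- tiny_model_config(seed = 11L, epochs = 2L)
  m1 <- train_model(build_model(cfg), parts$train, parts$validation)
  m2 <- train_model(build_model(cfg), parts$train, parts$validation)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, parts$validation)$.prob_acceptable,
                   predict(m2, parts$validation)$.prob_acceptable)
})

test_that("the sigmoid/binary-cross-entropy variant trains and bounds probabilities", {
  corp <- spectro_corpus(20, seed = 12)
  parts <- split_corpus(corp, c(0.8, 0.2, 0), seed = 13)
  cfg <- model_config(conv_blocks = list(c(8L, 3L)), dense_units = 8L,
                      lstm_units = 8L, head_units = 4L, output_units = 1L,
                      loss = "binary_cross_entropy", epochs = 2L,
                      patience = Inf, seed = 14L)
  m <- train_model(build_model(cfg), parts$train, parts$validation)
  p <- predict(m, parts$validation)
  expect_true(all(p$.prob_acceptable >= 0 & p$.prob_acceptable <= 1))
  expect_true(all(is.finite(m$history$loss)))
})

test_that("prediction ties at the threshold resolve to unacceptable", {
  corp <- spectro_corpus(4, seed = 15)
  m <- train_model(build_model(tiny_model_config(seed = 16L)), corp, corp,
                   epochs = 0L)
  p <- predict(m, corp)
  tie <- predict(m, corp, threshold = p$.prob_acceptable[1])
  expect_identical(as.character(tie$.pred_label[1]), "unacceptable")
  # empty input -> empty output
  empty <- predict(m, list())
  expect_identical(nrow(empty), 0L)
})

test_that("spectrogram shape mismatches name the offending record", {
  corp <- spectro_corpus(3, seed = 17)
  corp$spectrogram[[2]] <- corp$spectrogram[[2]][, 1:64]
  m <- build_model(tiny_model_config(seed = 18L))
  expect_error(predict(m, corp), regexp = corp$id[2], class = "ecgsqa_data_error")
})

test_that("save/load round-trips weights, config, history and predictions exactly", {
  corp <- spectro_corpus(16, seed = 19, snr_gap = c(15, -15))
  parts <- split_corpus(corp, c(0.75, 0.25, 0), seed = 20)
  m <- train_model(build_model(tiny_model_config(seed = 21L, epochs = 2L)),
                   parts$train, parts$validation)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$par, m$par)
  expect_equal(unclass(m2$config), unclass(m$config))
  expect_equal(as.data.frame(m2$history), as.data.frame(m$history))
  expect_identical(predict(m2, parts$validation)$.prob_acceptable,
                   predict(m, parts$validation)$.prob_acceptable)
  # saving twice produces identical bytes
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(m, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("corrupt or version-mismatched stores are load errors", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path)
  expect_error(load_model(path), class = "ecgsqa_load_error")
  m <- build_model(tiny_model_config(seed = 22L))
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(m, path2)
  txt <- sub("ecgsqa-model-1", "ecgsqa-model-0", readLines(path2))
  writeLines(txt, path2)
  expect_error(load_model(path2), class = "ecgsqa_load_error")
  expect_error(load_model(file.path(tempdir(), "absent.json")),
               class = "ecgsqa_load_error")
})

test_that("held-out F1 does not degrade as the class SNR gap widens", {
  f1_at_gap <- function(gap, seed) {
    train <- spectro_corpus(120, seed = seed, snr_gap = c(gap / 2, -gap / 2))
    test <- spectro_corpus(60, seed = seed + 1L, snr_gap = c(gap / 2, -gap / 2))
    parts <- split_corpus(train, c(0.85, 0.15, 0), seed = seed + 2L)
    m <- train_model(build_model(tiny_model_config(seed = seed + 3L, epochs = 8L)),
                     parts$train, parts$validation)
    glance(evaluate_model(m, test))$f1
  }
  f1s <- c(f1_at_gap(5, 100L), f1_at_gap(10, 200L), f1_at_gap(20, 300L))
  expect_true(all(diff(f1s) >= -1e-9))
})
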