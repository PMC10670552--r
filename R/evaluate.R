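# Confusion matrix and the four report metrics (sensitivity, specificity,
# accuracy, F1), with acceptable as the positive class by default.

#' Confusion matrix for binary quality labels
#'
#' @param truth,predicted Equal-length vectors of quality labels
#'   (`"acceptable"`/`"unacceptable"`).
#' @param positive Which class counts as positive (default `"acceptable"`;
#'   configurable so either reporting convention can be mirrored).
#' @return An `ecg_confusion` list with counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(rep("acceptable", 3), c("acceptable", "acceptable", "unacceptable"))
#' @export
confusion <- function(truth, predicted, positive = "acceptable") {
  truth <- as_quality(truth)
  predicted <- as_quality(predicted)
  if (length(truth) != length(predicted)) {
    abort(sprintf("`truth` (%d) and `predicted` (%d) differ in length.",
                  length(truth), length(predicted)),
          class = "ecgsqa_data_error")
  }
  if (length(truth) == 0L || anyNA(truth) || anyNA(predicted)) {
    abort("Labels must be non-empty and complete.", class = "ecgsqa_data_error")
  }
  if (!positive %in% quality_levels()) {
    abort("`positive` must be a quality level.", class = "ecgsqa_invalid_argument")
  }
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
                 tn = sum(!pos_t & !pos_p), fn = sum(pos_t & !pos_p),
                 positive = positive),
            class = "ecg_confusion")
}

#' @export
print.ecg_confusion <- function(x, ...) {
  cat(sprintf("<ecg_confusion> positive = %s\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity, accuracy and F1 from a confusion matrix
#'
#' `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)`, `Acc = (tp+tn)/total`,
#' `F1 = 2tp/(2tp+fp+fn)`, each expressed as a percentage. A metric with a
#' zero denominator is returned as `NA` and flagged in the `undefined`
#' column — it is never silently reported as 0.
#'
#' @param cm An [confusion()] object.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `f1` (percent), `undefined` (comma-separated
#'   names of undefined metrics, `""` if none).
#' @examples
#' qc_metrics(structure(list(tp = 9, fn = 1, tn = 8, fp = 2,
#'                           positive = "acceptable"),
#'                      class = "ecg_confusion"))
#' @export
qc_metrics <- function(cm) {
  if (!inherits(cm, "ecg_confusion")) {
    abort("`cm` must come from confusion().", class = "ecgsqa_invalid_argument")
  }
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0L) abort("Empty confusion matrix.", class = "ecgsqa_data_error")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  se <- ratio(cm$tp, cm$tp + cm$fn)
  sp <- ratio(cm$tn, cm$tn + cm$fp)
  acc <- 100 * (cm$tp + cm$tn) / total
  f1 <- ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  vals <- c(sensitivity = se, specificity = sp, accuracy = acc, f1 = f1)
  tibble::tibble(
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    sensitivity = se, specificity = sp, accuracy = acc, f1 = f1,
    undefined = paste(names(vals)[is.na(vals)], collapse = ",")
  )
}

#' Evaluate a trained model on a test corpus
#'
#' Runs [predict.ecg_model()], forms the confusion matrix against the true
#' labels, and computes the four report metrics. The report also carries the
#' observed test class ratio (and the training ratio, if supplied), so one
#' report corresponds to one row of a ratio-comparison table.
#'
#' @param model A trained `ecg_model`.
#' @param test Labeled test corpus with a `spectrogram` column.
#' @param threshold Decision threshold on the acceptable-class probability.
#' @param positive Positive class for Se/Sp/F1.
#' @param train_ratio Optional descriptor of the training class ratio
#'   (e.g. `"85:15"`) carried into the report.
#' @return An `ecg_eval` object.
#' @export
evaluate_model <- function(model, test, threshold = 0.5,
                           positive = "acceptable", train_ratio = NA_character_) {
  test <- as_ecg_tbl(test, require_label = TRUE, arg = "test")
  pred <- predict(model, test, threshold = threshold)
  cm <- confusion(test$label, pred$.pred_label, positive = positive)
  ratio <- class_ratio(test)
  structure(list(
    confusion = cm,
    metrics = qc_metrics(cm),
    test_ratio = sprintf("%.0f:%.0f", 100 * ratio$frac_acceptable,
                         100 * ratio$frac_unacceptable),
    train_ratio = train_ratio,
    n_test = nrow(test),
    threshold = threshold,
    predictions = tibble::as_tibble(pred[c("id", "label", ".prob_acceptable",
                                           ".pred_label")])
  ), class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<ecg_eval> n = %d | train ratio %s | test ratio %s\n",
              x$n_test, x$train_ratio, x$test_ratio))
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.2f%%", v)
  cat(sprintf("  Se %s  Sp %s  Acc %s  F1 %s\n",
              fmt(m$sensitivity), fmt(m$specificity), fmt(m$accuracy), fmt(m$f1)))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `ecg_eval`.
#' @param ... Unused.
#' @return Tibble with one row per metric: `metric`, `estimate` (percent).
#' @method tidy ecg_eval
#' @export
tidy.ecg_eval <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    metric = c("sensitivity", "specificity", "accuracy", "f1"),
    estimate = c(m$sensitivity, m$specificity, m$accuracy, m$f1)
  )
}

#' One-row summary of an evaluation report
#'
#' Mirrors one row of a ratio-comparison table: train ratio, test ratio and
#' the four metrics as percentages (reported to 2 decimals on printing).
#'
#' @param x An `ecg_eval`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance ecg_eval
#' @export
glance.ecg_eval <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    train_ratio = x$train_ratio, test_ratio = x$test_ratio, n = x$n_test,
    sensitivity = m$sensitivity, specificity = m$specificity,
    accuracy = m$accuracy, f1 = m$f1
  )
}

#' Plot an evaluation report
#'
#' Confusion-matrix heat map annotated with counts.
#'
#' @param object An `ecg_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_eval
#' @export
autoplot.ecg_eval <- function(object, ...) {
  cm <- object$confusion
  df <- data.frame(
    truth = factor(c("positive", "positive", "negative", "negative"),
                   levels = c("positive", "negative")),
    predicted = factor(c("positive", "negative", "positive", "negative"),
                       levels = c("positive", "negative")),
    n = c(cm$tp, cm$fn, cm$fp, cm$tn)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Positive class: %s", cm$positive)) +
    ggplot2::theme_minimal()
}

#' Write a ratio-comparison report table
#'
#' Formats one or more evaluation reports as a delimited-text table with
#' columns train ratio, test ratio, Se, Sp, Acc, F1 (percent, 2 decimals).
#'
#' @param reports A list of `ecg_eval` objects (or a single one).
#' @param path Optional output path (comma-separated text). When `NULL` the
#'   table is only returned.
#' @return The comparison tibble, invisibly when writing.
#' @export
report_table <- function(reports, path = NULL) {
  if (inherits(reports, "ecg_eval")) reports <- list(reports)
  tab <- dplyr::bind_rows(lapply(reports, glance))
  if (!is.null(path)) {
    out <- tab
    for (col in c("sensitivity", "specificity", "accuracy", "f1")) {
      out[[col]] <- ifelse(is.na(out[[col]]), "undef", sprintf("%.2f", out[[col]]))
    }
    utils::write.csv(as.data.frame(out), path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
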