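#' Build an ECG corpus tibble
#'
#' The package's working container is an ordinary tibble with one row per
#' single-lead record (or 10-s segment) and the waveform held in a
#' list-column, so corpora compose with dplyr verbs and the pipe.
#'
#' Columns:
#' \describe{
#'   \item{id}{unique record identifier}
#'   \item{samples}{list-column of numeric amplitude vectors}
#'   \item{fs}{sampling rate in Hz}
#'   \item{lead_id}{lead name within the source recording}
#'   \item{group_id}{identity of the source (e.g. 12-lead) recording; splits
#'     can be made group-aware so leads from one recording never straddle
#'     partitions}
#'   \item{label}{factor with levels `unacceptable`, `acceptable`, or `NA`
#'     for unlabeled data}
#' }
#'
#' @param samples List of numeric vectors, one per record.
#' @param fs Sampling rate(s) in Hz (recycled).
#' @param id,lead_id,group_id Character identifiers (defaults generated).
#' @param label Optional quality labels (`"acceptable"`/`"unacceptable"`).
#' @return A tibble of class `ecg_tbl`.
#' @examples
#' ecg_corpus(list(sin(1:500 / 10)), fs = 500)
#' @export
ecg_corpus <- function(samples, fs, id = NULL, lead_id = "lead1",
                       group_id = NULL, label = NA_character_) {
  if (!is.list(samples)) samples <- list(samples)
  n <- length(samples)
  if (n == 0L) abort("`samples` must contain at least one record.", class = "ecgsqa_invalid_argument")
  ok <- vapply(samples, function(s) is.numeric(s) && length(s) >= 1L && all(is.finite(s)), logical(1))
  if (!all(ok)) {
    abort("Every element of `samples` must be a non-empty finite numeric vector.",
          class = "ecgsqa_invalid_argument")
  }
  vapply(fs, check_scalar_number, numeric(1), name = "fs", positive = TRUE)
  id <- id %||% sprintf("rec%04d", seq_len(n))
  group_id <- group_id %||% id
  out <- tibble::tibble(
    id = as.character(rep_len(id, n)),
    samples = samples,
    fs = as.numeric(rep_len(fs, n)),
    lead_id = as.character(rep_len(lead_id, n)),
    group_id = as.character(rep_len(group_id, n)),
    label = as_quality(rep_len(label, n))
  )
  if (anyDuplicated(out$id)) {
    abort("Record ids must be unique within a corpus.", class = "ecgsqa_invalid_argument")
  }
  class(out) <- c("ecg_tbl", class(tibble::tibble()))
  out
}

as_ecg_tbl <- function(data, require_label = FALSE, arg = "data") {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    abort(sprintf("`%s` must be a non-empty data frame of ECG records.", arg),
          class = "ecgsqa_data_error")
  }
  needed <- c("id", "samples", "fs")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`%s` lacks required column(s): %s.", arg, paste(missing_cols, collapse = ", ")),
          class = "ecgsqa_data_error")
  }
  if (!"lead_id" %in% names(data)) data$lead_id <- "lead1"
  if (!"group_id" %in% names(data)) data$group_id <- data$id
  if (!"label" %in% names(data)) data$label <- NA_character_
  data$label <- as_quality(data$label)
  if (require_label && anyNA(data$label)) {
    abort(sprintf("`%s` must carry a quality label on every row.", arg),
          class = "ecgsqa_data_error")
  }
  if (!inherits(data, "ecg_tbl")) class(data) <- c("ecg_tbl", class(tibble::as_tibble(data)))
  data
}

#' Record durations in seconds
#'
#' @param data An ECG corpus tibble.
#' @return Numeric vector of per-record durations (`length(samples) / fs`).
#' @export
ecg_duration <- function(data) {
  data <- as_ecg_tbl(data)
  lengths(data$samples) / data$fs
}

#' Observed class ratio of a labeled corpus
#'
#' Proportions are recomputed from the label column on every call, never
#' cached, so they survive any dplyr manipulation of the corpus.
#'
#' @param data A labeled ECG corpus tibble.
#' @return One-row tibble with counts and fractions of each class
#'   (`frac_acceptable + frac_unacceptable == 1`).
#' @export
class_ratio <- function(data) {
  data <- as_ecg_tbl(data, require_label = TRUE)
  n_acc <- sum(data$label == "acceptable")
  n_una <- sum(data$label == "unacceptable")
  tibble::tibble(
    n = n_acc + n_una,
    n_acceptable = n_acc,
    n_unacceptable = n_una,
    frac_acceptable = n_acc / (n_acc + n_una),
    frac_unacceptable = n_una / (n_acc + n_una)
  )
}
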