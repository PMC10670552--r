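# Corpus assembly at controlled class ratios and train/validation/test
# splitting, with an optional group-aware (leakage-safe) mode.

#' Assemble a corpus at a requested class ratio
#'
#' Returns the largest corpus whose acceptable fraction equals
#' `ratio_acceptable` to within one sample, formed by keeping *all* of the
#' limiting class and uniformly subsampling the other — items are never
#' duplicated and never dropped from the limiting class. Formally it finds
#' the largest n with `round(n * r) <= n_acceptable_pool` and
#' `n - round(n * r) <= n_unacceptable_pool`.
#'
#' @param acceptable_pool,unacceptable_pool Labeled corpora (rows with other
#'   labels are rejected).
#' @param ratio_acceptable Target acceptable fraction, in (0, 1).
#' @param seed Integer seed for the subsampling.
#' @return An `ecg_tbl` combining the kept rows (acceptable first).
#' @examples
#' pool <- make_labeled_corpus(40, 0.5, seed = 1)
#' acc <- dplyr::filter(pool, label == "acceptable")
#' una <- dplyr::filter(pool, label == "unacceptable")
#' class_ratio(build_ratio_corpus(acc, una, 0.75, seed = 2))
#' @export
build_ratio_corpus <- function(acceptable_pool, unacceptable_pool,
                               ratio_acceptable, seed = 1L) {
  acceptable_pool <- as_ecg_tbl(acceptable_pool, require_label = TRUE,
                                arg = "acceptable_pool")
  unacceptable_pool <- as_ecg_tbl(unacceptable_pool, require_label = TRUE,
                                  arg = "unacceptable_pool")
  if (any(acceptable_pool$label != "acceptable")) {
    abort("`acceptable_pool` must contain only acceptable records.",
          class = "ecgsqa_data_error")
  }
  if (any(unacceptable_pool$label != "unacceptable")) {
    abort("`unacceptable_pool` must contain only unacceptable records.",
          class = "ecgsqa_data_error")
  }
  if (ratio_acceptable <= 0 || ratio_acceptable >= 1) {
    abort("`ratio_acceptable` must lie strictly between 0 and 1.",
          class = "ecgsqa_invalid_argument")
  }
  A <- nrow(acceptable_pool)
  U <- nrow(unacceptable_pool)
  n <- ratio_corpus_size(A, U, ratio_acceptable)
  if (n < 1L) {
    abort("Requested ratio not achievable from the supplied pools.",
          class = "ecgsqa_data_error")
  }
  n_acc <- as.integer(round(n * ratio_acceptable))
  n_una <- n - n_acc
  with_seed(seed, {
    keep_acc <- if (n_acc < A) sort(sample.int(A, n_acc)) else seq_len(A)
    keep_una <- if (n_una < U) sort(sample.int(U, n_una)) else seq_len(U)
    out <- dplyr::bind_rows(acceptable_pool[keep_acc, ],
                            unacceptable_pool[keep_una, ])
    class(out) <- c("ecg_tbl", class(tibble::tibble()))
    out
  })
}

# Largest n with round(n * r) <= A and n - round(n * r) <= U.
ratio_corpus_size <- function(A, U, r) {
  for (n in seq.int(A + U, 1L)) {
    n_acc <- round(n * r)
    if (n_acc >= 1L && (n - n_acc) >= 1L && n_acc <= A && (n - n_acc) <= U) {
      return(as.integer(n))
    }
  }
  0L
}

# Largest-remainder apportionment of n into parts proportional to fractions;
# the last partition absorbs the rounding residue direction by construction.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  residue <- n - sum(base)
  if (residue > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(residue)]] <- base[order_rem[seq_len(residue)]] + 1
  }
  as.integer(base)
}

#' Assign records to train/validation/test partitions
#'
#' Random partition into the requested fractions with largest-remainder
#' rounding (sizes exact to within one item). In group-aware mode every
#' `group_id` lands in a single partition, so leads from one source
#' recording can never straddle the train/test boundary.
#'
#' @param data A labeled ECG corpus tibble.
#' @param fractions Numeric triple (train, val, test), positive or zero,
#'   summing to 1.
#' @param seed Integer seed; identical seeds reproduce identical membership.
#' @param group_aware Keep whole `group_id`s together (default off,
#'   mirroring a plain random split).
#' @return The corpus with a `partition` factor column
#'   (train/validation/test).
#' @export
assign_partitions <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                              group_aware = FALSE) {
  data <- as_ecg_tbl(data)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three nonnegative numbers summing to 1.",
          class = "ecgsqa_invalid_argument")
  }
  n <- nrow(data)
  part_names <- c("train", "validation", "test")
  with_seed(seed, {
    if (!group_aware) {
      sizes <- largest_remainder(n, fractions)
      lab <- rep(part_names, times = sizes)
      data$partition <- factor(lab[order(sample.int(n))] , levels = part_names)
      # order(sample) above is a permutation-inverse trick; equivalent to
      # shuffling the labels uniformly.
    } else {
      groups <- unique(data$group_id)
      g_sizes <- table(data$group_id)[groups]
      target <- n * fractions
      if (max(g_sizes) > ceiling(target[1])) {
        abort(sprintf(
          "Group `%s` (%d items) exceeds the train partition target (%d); cannot split group-aware.",
          names(g_sizes)[which.max(g_sizes)], max(g_sizes), ceiling(target[1])),
          class = "ecgsqa_split_error")
      }
      ord <- sample(groups)
      filled <- c(train = 0, validation = 0, test = 0)
      g_part <- character(length(ord))
      names(g_part) <- ord
      for (g in ord) {
        # place the group where the relative deficit is largest
        deficit <- ifelse(target > 0, (target - filled) / pmax(target, 1), -Inf)
        pick <- part_names[which.max(deficit)]
        g_part[g] <- pick
        filled[pick] <- filled[pick] + g_sizes[[g]]
      }
      data$partition <- factor(g_part[data$group_id], levels = part_names)
    }
  })
  data
}

#' Split a corpus into train/validation/test corpora
#'
#' Convenience wrapper around [assign_partitions()] returning the three
#' disjoint corpora whose union is the input.
#'
#' @inheritParams assign_partitions
#' @return Named list of `ecg_tbl`s: `train`, `validation`, `test` (possibly
#'   zero-row).
#' @examples
#' corp <- make_labeled_corpus(20, 0.5, seed = 1)
#' sp <- split_corpus(corp, c(0.8, 0.1, 0.1), seed = 7)
#' vapply(sp, nrow, integer(1))
#' @export
split_corpus <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                         group_aware = FALSE) {
  assigned <- assign_partitions(data, fractions, seed, group_aware)
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(p) {
                  part <- assigned[assigned$partition == p,
                                   setdiff(names(assigned), "partition")]
                  class(part) <- c("ecg_tbl", class(tibble::tibble()))
                  part
                })
  out
}

#' Write / read a corpus manifest
#'
#' Plain-text (comma-separated) listing of a corpus: one row per record with
#' `id`, `label`, `group_id` and, when present, `partition` — enough to
#' reconstruct corpus membership exactly.
#'
#' @param data A corpus tibble (optionally carrying `partition`).
#' @param path Output path.
#' @return `path` invisibly; `read_corpus_manifest()` returns a tibble.
#' @export
write_corpus_manifest <- function(data, path) {
  data <- as_ecg_tbl(data)
  cols <- intersect(c("id", "label", "group_id", "partition"), names(data))
  utils::write.csv(as.data.frame(data[cols]), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_corpus_manifest
#' @export
read_corpus_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Manifest not found: %s", path), class = "ecgsqa_format_error")
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
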