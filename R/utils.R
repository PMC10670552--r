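# Internal helpers shared across modules.

#' @importFrom rlang abort %||%
NULL

# Run `expr` with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

check_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "ecgsqa_invalid_argument")
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name), class = "ecgsqa_invalid_argument")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name), class = "ecgsqa_invalid_argument")
  }
  invisible(x)
}

# Mean signal power; the DC level is part of the signal by convention here.
signal_power <- function(x) mean(x^2)

#' Quality label levels
#'
#' Canonical encoding of the binary quality classes. The unacceptable class is
#' level 1 (integer code 0 in the model) and acceptable is level 2 (code 1).
#'
#' @return Character vector `c("unacceptable", "acceptable")`.
#' @export
quality_levels <- function() c("unacceptable", "acceptable")

as_quality <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% quality_levels()
  if (any(bad)) {
    abort(sprintf("Unknown quality label(s): %s", paste(unique(x[bad]), collapse = ", ")),
          class = "ecgsqa_data_error")
  }
  factor(x, levels = quality_levels())
}
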