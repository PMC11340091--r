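# Internal helpers: hierarchical seed derivation and validation.

#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic component of the package (clinical draws, expression
#' draws, fold assignment, every permutation) consumes its own sub-stream
#' seed derived from a single master seed and a component key, so that a
#' partial change to a configuration leaves unrelated draws untouched.
#'
#' @param seed master integer seed.
#' @param ... component keys (strings and/or integers) identifying the
#'   sub-stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 48271 + as.numeric(k) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}

#' Validate a raw count matrix
#'
#' @param counts numeric matrix, features x samples, with unique row and
#'   column names.
#' @return The matrix, invisibly, after validation.
#' @keywords internal
check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (features x samples)")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("`counts` must have at least one feature and one sample")
  if (anyNA(counts) || any(counts < 0))
    stop("`counts` must be non-negative with no missing values")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("`counts` must contain integer counts")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("`counts` must have unique feature (row) names")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("`counts` must have unique sample (column) names")
  invisible(counts)
}

check_outcome <- function(time, event) {
  if (length(time) != length(event))
    stop("`time` and `event` must have the same length")
  if (anyNA(time) || anyNA(event)) stop("survival outcome contains missing values")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("`event` must be coded 0/1")
  invisible(NULL)
}

# Quantile convention used by every filter in the package: linear
# interpolation of order statistics (stats::quantile type 7).
q_filter <- function(x, p) unname(quantile(x, probs = p, type = 7, names = FALSE))
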