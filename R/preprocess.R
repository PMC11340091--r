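# Unsupervised count filtering, TMM normalization and Blom transformation.

#' Filter low-abundance miRNAs by third-quartile count
#'
#' Removes miRNAs whose third quartile across samples is below a count
#' threshold: a feature is retained when `Q3 >= q3_threshold` ("fewer
#' than five counts" excluded at the default). Quartiles use linear
#' interpolation of order statistics (`stats::quantile` type 7), the same
#' convention as [filter_samples()].
#'
#' @param counts integer matrix, miRNAs x samples.
#' @param q3_threshold minimum third-quartile count for retention.
#' @return The retained submatrix (row order preserved), with a
#'   `provenance` attribute recording the threshold and removal tally.
#'   Warns and returns a 0-row matrix if nothing survives.
#' @export
filter_mirnas <- function(counts, q3_threshold = 5) {
  check_count_matrix(counts)
  q3 <- apply(counts, 1, q_filter, p = 0.75)
  keep <- q3 >= q3_threshold
  if (!any(keep))
    warning("all miRNAs removed by the Q3 filter (threshold ", q3_threshold, ")")
  out <- counts[keep, , drop = FALSE]
  attr(out, "provenance") <- list(filter = "mirna_q3", q3_threshold = q3_threshold,
                                  n_in = nrow(counts), n_removed = sum(!keep))
  out
}

#' Filter samples with degenerate count distributions
#'
#' Removes samples whose across-miRNA median or first quartile equals
#' zero (applied after [filter_mirnas()], matching the pipeline order).
#'
#' @param counts integer matrix, miRNAs x samples.
#' @return The retained submatrix (column order preserved) with a
#'   `provenance` attribute. Errors, with per-sample quartile
#'   diagnostics, if every sample would be removed.
#' @export
filter_samples <- function(counts) {
  check_count_matrix(counts)
  med <- apply(counts, 2, q_filter, p = 0.50)
  q1 <- apply(counts, 2, q_filter, p = 0.25)
  keep <- med > 0 & q1 > 0
  if (!any(keep)) {
    diag <- paste0(colnames(counts), ": median=", signif(med, 3),
                   ", Q1=", signif(q1, 3), collapse = "; ")
    stop("all samples removed by the median/Q1 filter [", diag, "]")
  }
  out <- counts[, keep, drop = FALSE]
  attr(out, "provenance") <- list(filter = "sample_median_q1",
                                  n_in = ncol(counts), n_removed = sum(!keep))
  out
}

#' TMM normalization factors
#'
#' Per-sample scaling factors by the trimmed mean of M-values: pairwise
#' log-ratios against a reference sample (the one whose upper quartile of
#' counts-per-total is closest to the mean upper quartile), doubly
#' trimmed on log-ratio and absolute expression, weighted by inverse
#' asymptotic (delta-method binomial) variances, and rescaled so the
#' factors multiply to 1. Computed via `edgeR::calcNormFactors`.
#'
#' @param counts integer matrix, miRNAs x samples; every sample must have
#'   a positive library size.
#' @param logratio_trim two-sided trim fraction on M-values.
#' @param abs_trim two-sided trim fraction on average expression.
#' @return Named per-sample factors with geometric mean 1.
#' @export
tmm_normalization_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim, sumTrim = abs_trim)
  setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts-per-million with effective library sizes
#'
#' `log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)`, where
#' the effective library size is the raw library size times the TMM
#' factor and a fixed pseudocount keeps zeros finite while preserving
#' within-sample ordering.
#'
#' @param counts integer matrix, miRNAs x samples.
#' @param factors per-sample normalization factors (e.g. from
#'   [tmm_normalization_factors()]).
#' @param prior_count pseudocount added to every count.
#' @return Real matrix of log2-CPM values.
#' @export
normalize_counts <- function(counts, factors, prior_count = 0.5) {
  check_count_matrix(counts)
  if (length(factors) != ncol(counts)) stop("one factor per sample required")
  if (any(factors <= 0)) stop("normalization factors must be positive")
  eff <- colSums(counts) * factors
  log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
}

#' Blom rank-based inverse-normal transformation
#'
#' Maps a vector to approximate standard-normal scores:
#' `qnorm((r - c) / (n - 2c + 1))` with tie-averaged ranks `r` and the
#' Blom offset `c = 3/8`. A constant vector maps to all zeros.
#'
#' @param x numeric vector, length >= 2.
#' @param offset_c rank offset; 3/8 is the Blom convention.
#' @return Numeric vector of normal scores.
#' @export
blom_transform <- function(x, offset_c = 3 / 8) {
  n <- length(x)
  if (n < 2) stop("Blom transformation needs at least 2 values")
  if (anyNA(x)) stop("missing values in `x`")
  r <- rank(x, ties.method = "average")
  qnorm((r - offset_c) / (n - 2 * offset_c + 1))
}

#' Full preprocessing pipeline for a raw count matrix
#'
#' Applies, in order: the third-quartile miRNA filter, the median/Q1
#' sample filter, TMM normalization, log2-CPM, and the Blom
#' transformation of every miRNA across samples. Because the Blom step is
#' rank-based, the choice of log-CPM as its input only matters through
#' how the pseudocount breaks ties among zero counts.
#'
#' @param counts integer matrix, miRNAs x samples.
#' @param q3_threshold passed to [filter_mirnas()].
#' @param logratio_trim,abs_trim passed to [tmm_normalization_factors()].
#' @param prior_count passed to [normalize_counts()].
#' @return An object of class `mirna_expression`: list with `expression`
#'   (Blom-transformed matrix), `logcpm`, `counts` (filtered),
#'   `normalization_factors` and `provenance` (filter tallies and all
#'   parameters).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 30, n_mirnas = 150,
#'                                             seed = 3))
#' prep <- preprocess_counts(cohort$counts)
#' prep$provenance$n_mirnas_retained
#' @export
preprocess_counts <- function(counts, q3_threshold = 5, logratio_trim = 0.3,
                              abs_trim = 0.05, prior_count = 0.5) {
  filtered <- filter_mirnas(counts, q3_threshold)
  if (nrow(filtered) == 0) stop("no miRNAs left after the Q3 filter")
  mirna_prov <- attr(filtered, "provenance")
  filtered <- filter_samples(filtered)
  sample_prov <- attr(filtered, "provenance")
  factors <- tmm_normalization_factors(filtered, logratio_trim, abs_trim)
  logcpm <- normalize_counts(filtered, factors, prior_count)
  expr <- t(apply(logcpm, 1, blom_transform))
  dimnames(expr) <- dimnames(logcpm)
  structure(list(expression = expr,
                 logcpm = logcpm,
                 counts = filtered,
                 normalization_factors = factors,
                 provenance = list(q3_threshold = q3_threshold,
                                   logratio_trim = logratio_trim,
                                   abs_trim = abs_trim,
                                   prior_count = prior_count,
                                   quantile_type = 7,
                                   n_mirnas_in = mirna_prov$n_in,
                                   n_mirnas_removed = mirna_prov$n_removed,
                                   n_mirnas_retained = nrow(filtered),
                                   n_samples_in = sample_prov$n_in,
                                   n_samples_removed = sample_prov$n_removed,
                                   n_samples_retained = ncol(filtered))),
            class = "mirna_expression")
}

#' @export
print.mirna_expression <- function(x, ...) {
  p <- x$provenance
  cat("Normalized miRNA expression matrix\n")
  cat(sprintf("  miRNAs: %d retained of %d (Q3 >= %g filter)\n",
              p$n_mirnas_retained, p$n_mirnas_in, p$q3_threshold))
  cat(sprintf("  samples: %d retained of %d (median/Q1 > 0 filter)\n",
              p$n_samples_retained, p$n_samples_in))
  cat("  scale: TMM-normalized log2-CPM, Blom-transformed per miRNA\n")
  invisible(x)
}
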