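# Screen of miRNA expression against clinical covariates.

#' Two-sample t-tests of every miRNA against a binary covariate
#'
#' Tests each miRNA's transformed expression for a mean difference
#' between two covariate-defined groups, with pooled-variance (Student)
#' t-tests by default and Benjamini-Hochberg adjustment across all
#' miRNAs within the contrast. Multi-level covariates should be
#' dichotomized by the caller (e.g. extreme categories).
#'
#' @param expr numeric matrix, miRNAs x samples (normalized/transformed
#'   scale), or a `mirna_expression` object.
#' @param labels binary group labels aligned to the samples (factor,
#'   character or logical; the second level is the reference subtracted
#'   in `mean_diff`).
#' @param welch use the Welch unequal-variance test instead of the
#'   pooled-variance Student test.
#' @return A data frame of class `association_table`: one row per miRNA
#'   with `mirna_id`, `mean_diff` (group1 - group2), `t`, `df`, `p`,
#'   `p_adj` (BH), `n1`, `n2`, sorted by `p`.
#' @export
mirna_covariate_ttests <- function(expr, labels, welch = FALSE) {
  if (inherits(expr, "mirna_expression")) expr <- expr$expression
  expr <- as.matrix(expr)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2) stop("`labels` must have exactly two levels")
  if (length(labels) != ncol(expr)) stop("one label per sample required")
  i1 <- which(labels == levels(labels)[1])
  i2 <- which(labels == levels(labels)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 samples")

  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1, var)
  v2 <- apply(expr[, i2, drop = FALSE], 1, var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tstat <- (m1 - m2) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- rep(n1 + n2 - 2, nrow(expr))
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  tstat[!is.finite(tstat)] <- 0   # zero-variance, zero-difference rows
  p <- 2 * pt(-abs(tstat), df)
  out <- data.frame(mirna_id = rownames(expr), mean_diff = m1 - m2,
                    t = tstat, df = df, p = p,
                    p_adj = p.adjust(p, method = "BH"),
                    n1 = n1, n2 = n2, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$p), ]
  class(out) <- c("association_table", "data.frame")
  out
}
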