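# Permutation nulls for the cross-validated log-rank statistic, the
# landmark AUC, and the added predictive value of the miRNA block over
# clinical factors.

perm_pvalue <- function(observed, null_draws) {
  # add-one permutation p-value: strictly positive and valid
  (1 + sum(null_draws >= observed)) / (length(null_draws) + 1)
}

new_permutation_result <- function(statistic_name, observed, null_draws, seed) {
  structure(list(statistic_name = statistic_name, observed = observed,
                 null_draws = null_draws, B = length(null_draws),
                 p_value = perm_pvalue(observed, null_draws), seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("Permutation test of %s: observed = %.4f, B = %d, p = %.4g\n",
              x$statistic_name, x$observed, x$B, x$p_value))
  invisible(x)
}

# One full run of the CV procedure for a model: folds, nested lambda,
# out-of-fold scoring, log-rank statistic and landmark AUC.
cv_model_statistics <- function(X, time, event, fitter, k = 5, alpha = 0.9,
                                landmark = 24, seed = 1L,
                                control = penalized_control(), folds = NULL,
                                keep_cvpi = FALSE) {
  if (is.null(folds)) folds <- make_folds(event, k = k, seed = derive_seed(seed, "folds"))
  cvpi <- cv_prognostic_indices(X, time, event, fitter = fitter, folds = folds,
                                alpha = alpha, inner_k = k,
                                seed = derive_seed(seed, "inner"),
                                control = control)
  lr <- logrank_test(time, event, cvpi$scores$group)
  roc <- cv_landmark_roc(cvpi$scores$score, time, event, landmark = landmark)
  out <- list(logrank = lr$statistic, auc = roc$auc, folds = folds)
  if (keep_cvpi) out$cvpi <- cvpi
  out
}

#' Permutation null for the CV log-rank statistic and landmark AUC
#'
#' Tests whether a model's cross-validated risk discrimination exceeds
#' chance: the correspondence between the (time, event) pairs and the
#' covariate rows is randomly permuted and the entire cross-validation
#' procedure — fold creation, nested penalty selection, out-of-fold
#' scoring, statistic — is repeated for every permutation. Because times
#' and event indicators travel together, every permuted dataset has the
#' observed marginal outcome distribution. One-sided add-one p-values:
#' `(1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param X numeric matrix, patients x predictors.
#' @param time,event survival outcome.
#' @param fitter `"penalized"` or `"standard"` (see
#'   [cv_prognostic_indices()]).
#' @param B number of permutations.
#' @param seed master seed; folds and each permutation consume derived
#'   streams.
#' @param k folds for the outer and inner CV.
#' @param alpha elastic-net mixing parameter.
#' @param landmark landmark months for the AUC.
#' @param control a [penalized_control()].
#' @param refold re-draw the CV folds inside every permutation (default,
#'   the full re-run of the procedure); `FALSE` freezes the observed
#'   folds.
#' @return List with elements `cv_logrank` and `cv_auc`, each a
#'   `permutation_test_result`, plus `observed` (the observed CV run).
#' @export
permute_full_null <- function(X, time, event, fitter = c("penalized", "standard"),
                              B = 500, seed = 1L, k = 5, alpha = 0.9,
                              landmark = 24, control = penalized_control(),
                              refold = TRUE) {
  fitter <- match.arg(fitter)
  X <- as.matrix(X)
  check_outcome(time, event)
  if (B < 1) stop("`B` must be at least 1")
  n <- nrow(X)
  obs <- cv_model_statistics(X, time, event, fitter, k = k, alpha = alpha,
                             landmark = landmark, seed = derive_seed(seed, "obs"),
                             control = control, keep_cvpi = TRUE)
  null_lr <- null_auc <- numeric(B)
  for (b in seq_len(B)) {
    perm <- withr::with_seed(derive_seed(seed, "shuffle", b), sample.int(n))
    st <- cv_model_statistics(X, time[perm], event[perm], fitter, k = k,
                              alpha = alpha, landmark = landmark,
                              seed = derive_seed(seed, "perm", b),
                              control = control,
                              folds = if (refold) NULL else obs$folds)
    null_lr[b] <- st$logrank
    null_auc[b] <- st$auc
  }
  list(cv_logrank = new_permutation_result("cv_logrank", obs$logrank, null_lr, seed),
       cv_auc = new_permutation_result("cv_auc", obs$auc, null_auc, seed),
       observed = obs)
}

#' Permutation test of the miRNAs' added predictive value
#'
#' Compares the combined model (miRNA + clinical, elastic-net Cox) with
#' the clinical-only model (standard Cox) on shared cross-validation
#' folds, using the differences in CV log-rank statistic and landmark
#' AUC. The null distribution permutes only the rows of the miRNA block
#' — whole patients at a time, preserving the inter-miRNA correlation —
#' while the clinical block and the outcome stay fixed, and re-runs the
#' combined model's full CV for each permutation; the clinical-only
#' statistic is unchanged by construction and computed once. Folds are
#' held fixed across permutations so the identity permutation reproduces
#' the observed statistic exactly.
#'
#' @param X_clinical clinical design matrix (patients x factors).
#' @param X_mirna miRNA expression matrix (patients x miRNAs).
#' @param time,event survival outcome.
#' @param B number of permutations.
#' @param seed master seed.
#' @param k CV folds.
#' @param alpha elastic-net mixing parameter.
#' @param landmark landmark months.
#' @param control a [penalized_control()].
#' @param permutations optional list of explicit permutation index
#'   vectors (length-`B`), e.g. for audits; `NULL` draws them from the
#'   seed's stream.
#' @return List with `delta_logrank` and `delta_auc`
#'   (`permutation_test_result`s, one-sided for improvement), plus
#'   `model2` and `model3` observed CV statistics.
#' @export
added_value_test <- function(X_clinical, X_mirna, time, event, B = 500,
                             seed = 1L, k = 5, alpha = 0.9, landmark = 24,
                             control = penalized_control(), permutations = NULL) {
  X_clinical <- as.matrix(X_clinical)
  X_mirna <- as.matrix(X_mirna)
  check_outcome(time, event)
  if (nrow(X_clinical) != nrow(X_mirna))
    stop("clinical and miRNA blocks must cover the same patients")
  if (B < 1) stop("`B` must be at least 1")
  if (!is.null(permutations) && length(permutations) != B)
    stop("`permutations` must contain B index vectors")
  n <- nrow(X_mirna)

  folds <- make_folds(event, k = k, seed = derive_seed(seed, "folds"))
  run_m2 <- function(Xm) {
    cv_model_statistics(cbind(X_clinical, Xm), time, event, "penalized",
                        k = k, alpha = alpha, landmark = landmark,
                        seed = derive_seed(seed, "m2"), control = control,
                        folds = folds)
  }
  m3 <- cv_model_statistics(X_clinical, time, event, "standard", k = k,
                            alpha = alpha, landmark = landmark,
                            seed = derive_seed(seed, "m3"), control = control,
                            folds = folds)
  m2 <- run_m2(X_mirna)

  null_dlr <- null_dauc <- numeric(B)
  for (b in seq_len(B)) {
    perm <- if (is.null(permutations)) {
      withr::with_seed(derive_seed(seed, "shuffle", b), sample.int(n))
    } else permutations[[b]]
    st <- run_m2(X_mirna[perm, , drop = FALSE])
    null_dlr[b] <- st$logrank - m3$logrank
    null_dauc[b] <- st$auc - m3$auc
  }
  list(delta_logrank = new_permutation_result("delta_logrank",
                                              m2$logrank - m3$logrank,
                                              null_dlr, seed),
       delta_auc = new_permutation_result("delta_auc", m2$auc - m3$auc,
                                          null_dauc, seed),
       model2 = m2[c("logrank", "auc")], model3 = m3[c("logrank", "auc")])
}
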