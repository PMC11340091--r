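# Cross-validated predictive-accuracy machinery: out-of-fold prognostic
# indices (pre-validation), median-split CV Kaplan-Meier curves, and the
# IPCW time-dependent ROC at a landmark timepoint.

#' Event-stratified cross-validation folds
#'
#' Deals patients into `k` folds of near-equal size so that the number of
#' events per fold differs by at most one (avoids training folds with no
#' events at small sample sizes). Deterministic given the seed. Set
#' `stratify = FALSE` for plain random folds.
#'
#' @param event event indicator vector (defines both n and the strata).
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratify stratify on the event indicator.
#' @return Integer fold id (1..k) per patient.
#' @export
make_folds <- function(event, k = 5, seed = 1L, stratify = TRUE) {
  n <- length(event)
  if (k < 2 || k > n) stop("`k` must be between 2 and the number of patients")
  withr::with_seed(as.integer(seed), {
    cycle <- rep_len(sample.int(k), n)     # balanced fold sequence
    folds <- integer(n)
    if (stratify) {
      ord <- c(sample(which(event == 1)), sample(which(event == 0)))
    } else {
      ord <- sample.int(n)
    }
    folds[ord] <- cycle
    folds
  })
}

#' Model specification for the three-model analysis
#'
#' Model 1 uses the miRNA block only and Model 2 the miRNA and clinical
#' blocks, both fitted by elastic-net penalized Cox with the penalty
#' selected by inner cross-validation; Model 3 uses the clinical block
#' only, fitted by standard Cox regression.
#'
#' @param name one of `"model1_mirna_only"`, `"model2_combined"`,
#'   `"model3_clinical_only"`.
#' @return List of class `model_spec` with `name`, `blocks`, `fitter`.
#' @export
model_spec <- function(name = c("model1_mirna_only", "model2_combined",
                                "model3_clinical_only")) {
  name <- match.arg(name)
  blocks <- switch(name,
                   model1_mirna_only = "mirna",
                   model2_combined = c("clinical", "mirna"),
                   model3_clinical_only = "clinical")
  fitter <- if (name == "model3_clinical_only") "standard" else "penalized"
  structure(list(name = name, blocks = blocks, fitter = fitter),
            class = "model_spec")
}

#' Clinical design matrix
#'
#' Encodes the standard prognostic factors the way the multivariable
#' models use them: sex as an M-vs-F dummy, age in years as a continuous
#' 1-unit-increment covariate, and pathological stage as two dummies (II
#' vs I, IIIA vs I).
#'
#' @param clinical data frame with columns `age`, `sex` (`"M"`/`"F"`),
#'   `stage` (`"I"`/`"II"`/`"IIIA"`).
#' @return Numeric matrix with columns `sex_m`, `age`, `stage_ii`,
#'   `stage_iiia`.
#' @export
clinical_design <- function(clinical) {
  stopifnot(all(c("age", "sex", "stage") %in% names(clinical)))
  if (!all(clinical$stage %in% c("I", "II", "IIIA")))
    stop("`stage` must be one of I, II, IIIA")
  cbind(sex_m = as.numeric(clinical$sex == "M"),
        age = as.numeric(clinical$age),
        stage_ii = as.numeric(clinical$stage == "II"),
        stage_iiia = as.numeric(clinical$stage == "IIIA"))
}

#' Out-of-fold prognostic indices (pre-validation)
#'
#' For each fold, the model is fitted on the remaining folds — penalized
#' models select their lambda by an inner 5-fold cross-validation on the
#' training portion only — and the held-out patients are scored with the
#' resulting coefficients. Every patient is therefore scored exactly once
#' by a model that never saw their outcome. Risk groups split the pooled
#' out-of-fold scores at their median, patients at or below the median
#' going to the low-risk group (so constant scores deterministically
#' yield a single low-risk group).
#'
#' @param X numeric matrix, patients x predictors.
#' @param time,event survival outcome.
#' @param fitter `"penalized"` (elastic net, inner-CV lambda) or
#'   `"standard"` (unpenalized Cox).
#' @param folds integer fold assignment from [make_folds()].
#' @param alpha elastic-net mixing parameter.
#' @param inner_k folds of the inner lambda-selection CV.
#' @param seed seed for the inner CV fold streams.
#' @param control a [penalized_control()].
#' @return Object of class `cv_prognostic_index`: data frame `scores`
#'   (`score`, `fold`, `group` per patient, in input order), list
#'   `fold_coefficients`, the split `median`, and the call parameters.
#' @export
cv_prognostic_indices <- function(X, time, event,
                                  fitter = c("penalized", "standard"),
                                  folds, alpha = 0.9, inner_k = 5, seed = 1L,
                                  control = penalized_control()) {
  fitter <- match.arg(fitter)
  X <- as.matrix(X)
  check_outcome(time, event)
  if (anyNA(X)) stop("`X` must be complete-case before cross-validation")
  if (length(folds) != nrow(X)) stop("`folds` must assign every patient")
  k <- max(folds)
  score <- rep(NA_real_, nrow(X))
  fold_coefficients <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (sum(event[tr]) == 0)
      stop("training portion for fold ", f, " has zero events")
    if (fitter == "penalized") {
      sel <- select_lambda_cv(X[tr, , drop = FALSE], time[tr], event[tr],
                              k = inner_k, alpha = alpha,
                              seed = derive_seed(seed, "inner", f),
                              control = control)
      beta <- sel$fit$beta
    } else {
      beta <- fit_cox(X[tr, , drop = FALSE], time[tr], event[tr])$beta
    }
    fold_coefficients[[f]] <- beta
    score[te] <- drop(X[te, , drop = FALSE] %*% beta)
  }
  med <- median(score)
  group <- ifelse(score > med, "high", "low")
  structure(list(scores = data.frame(score = score, fold = folds,
                                     group = group, stringsAsFactors = FALSE),
                 fold_coefficients = fold_coefficients,
                 median = med, fitter = fitter, alpha = alpha, k = k),
            class = "cv_prognostic_index")
}

#' @export
print.cv_prognostic_index <- function(x, ...) {
  cat(sprintf("Cross-validated prognostic index (%s fitter, %d folds)\n",
              x$fitter, x$k))
  cat(sprintf("  risk groups at pooled median %.3f: low=%d, high=%d\n",
              x$median, sum(x$scores$group == "low"),
              sum(x$scores$group == "high")))
  invisible(x)
}

#' Cross-validated Kaplan-Meier curves and log-rank statistic
#'
#' Kaplan-Meier curves of the low/high out-of-fold risk groups, plus the
#' log-rank chi-square statistic on the pooled curves. Because group
#' membership is itself an output of cross-validation, the statistic's
#' null distribution is not chi-square; it is returned untransformed and
#' its significance is assessed by permutation (see
#' [permute_full_null()]).
#'
#' @param cvpi a [cv_prognostic_indices()] result.
#' @param time,event survival outcome in the same patient order.
#' @return List with `curves` (a `km_estimate`) and `statistic`.
#' @export
cv_km_logrank <- function(cvpi, time, event) {
  stopifnot(inherits(cvpi, "cv_prognostic_index"))
  g <- cvpi$scores$group
  lr <- logrank_test(time, event, g)
  list(curves = km_estimate(time, event, g), statistic = lr$statistic)
}

#' Cross-validated time-dependent ROC at a landmark timepoint
#'
#' Cumulative-case / dynamic-control ROC at the landmark: cases are
#' patients with an event by the landmark, controls are patients still
#' event-free beyond it. Censoring is handled by inverse-probability-of-
#' censoring weights from the reverse Kaplan-Meier estimate of the
#' censoring distribution: a case observed at time `t` gets weight
#' `1/G(t-)` and every control gets weight `1/G(landmark)`; patients
#' censored before the landmark contribute nothing. The AUC is the
#' trapezoidal integral of the curve, equal to the weighted concordance
#' with ties counted 1/2.
#'
#' @param scores risk scores (higher = higher hazard), or a
#'   `cv_prognostic_index`.
#' @param time,event survival outcome.
#' @param landmark landmark timepoint in months.
#' @return Object of class `roc_result`: `fp`, `tp` (curve coordinates
#'   from (0,0) to (1,1)), `auc`, `landmark`, `n_cases`, `n_controls`.
#' @export
cv_landmark_roc <- function(scores, time, event, landmark = 24) {
  if (inherits(scores, "cv_prognostic_index")) scores <- scores$scores$score
  check_outcome(time, event)
  if (length(scores) != length(time)) stop("`scores` must align with the outcome")

  cases <- which(event == 1 & time <= landmark)
  controls <- which(time > landmark)
  if (length(cases) == 0) stop("no cases (events by the landmark)")
  if (length(controls) == 0) stop("no controls (event-free beyond the landmark)")

  # censoring survival G from the reverse KM; G(t-) via strictly-smaller lookup
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gstep <- c(1, cfit$surv)
  G_at <- function(t) Gstep[findInterval(t, cfit$time) + 1L]          # G(t)
  G_before <- function(t) Gstep[findInterval(t, cfit$time, left.open = TRUE) + 1L] # G(t-)

  w_case <- 1 / G_before(time[cases])
  g_land <- G_at(landmark)
  if (any(!is.finite(w_case)) || g_land <= 0)
    stop("IPCW weights are degenerate: censoring distribution reaches zero before the landmark")
  w_ctrl <- rep(1 / g_land, length(controls))

  s_case <- scores[cases]
  s_ctrl <- scores[controls]
  thr <- sort(unique(scores[c(cases, controls)]), decreasing = TRUE)
  tp <- c(0, vapply(thr, function(ct) sum(w_case[s_case >= ct]), 0)) / sum(w_case)
  fp <- c(0, vapply(thr, function(ct) sum(w_ctrl[s_ctrl >= ct]), 0)) / sum(w_ctrl)
  auc <- sum(diff(fp) * (head(tp, -1) + tp[-1]) / 2)

  structure(list(fp = fp, tp = tp, auc = auc, landmark = landmark,
                 n_cases = length(cases), n_controls = length(controls)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("IPCW time-dependent ROC at %g months: AUC = %.3f (%d cases, %d controls)\n",
              x$landmark, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}
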