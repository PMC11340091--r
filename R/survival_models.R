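# Kaplan-Meier estimation, log-rank testing, standard and elastic-net
# penalized Cox regression. Estimation is delegated to the survival and
# glmnet packages; this layer fixes the conventions used throughout the
# pipeline (Breslow ties, event-stratified folds, minimum-deviance lambda).

#' Kaplan-Meier estimate, overall or per group
#'
#' Product-limit estimator with simultaneous decrement at tied event
#' times. The median is the smallest time at which the survival curve
#' drops to 0.5 or below, or `NA` when not reached.
#'
#' @param time follow-up times in months.
#' @param event event indicator (1 = relapse/death, 0 = censored).
#' @param group optional group labels; one curve per level.
#' @return An object of class `km_estimate`: named list of curves, each
#'   with `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `median`, `n`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_outcome(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  if (length(group) != length(time)) stop("`group` must match `time` in length")
  if (any(table(group) < 1)) stop("empty group")
  curves <- lapply(split(seq_along(time), group), function(idx) {
    fit <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    med <- unname(quantile(fit, probs = 0.5)$quantile)
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, surv = fit$surv, median = med,
         n = length(idx))
  })
  structure(curves, class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  for (g in names(x)) {
    med <- x[[g]]$median
    cat(sprintf("  %s: n=%d, events=%d, median=%s\n", g, x[[g]]$n,
                sum(x[[g]]$n_event),
                if (is.na(med)) "NR" else sprintf("%.1f", med)))
  }
  invisible(x)
}

#' Log-rank test comparing survival between groups
#'
#' Standard observed-minus-expected chi-square statistic with
#' `(number of groups - 1)` degrees of freedom. With fewer than two
#' distinct groups the statistic is 0 and p = 1 (the degenerate case a
#' constant cross-validated score produces).
#'
#' @param time,event survival outcome.
#' @param group group labels.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  check_outcome(time, event)
  g <- factor(group)
  if (nlevels(droplevels(g)) < 2)
    return(list(statistic = 0, df = 0L, p_value = 1))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(droplevels(g)) - 1L
  list(statistic = unname(sd_fit$chisq), df = df,
       p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Applies the Kaplan-Meier estimator with the censoring indicator
#' inverted (censored patients become "events"), so events are censored
#' observations of the potential follow-up time; returns the median of
#' that curve.
#'
#' @param time,event survival outcome.
#' @return Median follow-up in months, or `NA` when not reached (e.g.
#'   when every patient had an event).
#' @export
reverse_km_median_followup <- function(time, event) {
  check_outcome(time, event)
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  unname(quantile(fit, probs = 0.5)$quantile)
}

#' Standard Cox proportional hazards fit
#'
#' Maximizes the Breslow-approximation partial likelihood; Wald
#' confidence intervals `exp(beta +/- 1.96 SE)`.
#'
#' @param X numeric matrix, patients x predictors, with column names.
#' @param time,event survival outcome aligned to the rows of `X`.
#' @return An object of class `cox_fit`: `beta`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value` (all named by predictor), `loglik`, `n`,
#'   `n_event`, plus the underlying `coxph` fit. Aliased (perfectly
#'   collinear) columns get coefficient 0 with `NA` inference.
#' @export
fit_cox <- function(X, time, event) {
  X <- as.matrix(X)
  check_outcome(time, event)
  if (nrow(X) != length(time)) stop("rows of `X` must align with the outcome")
  if (sum(event) < 1) stop("at least one event is required")
  if (any(apply(X, 2, var) == 0)) stop("constant predictor column(s) in `X`")
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow"),
    warning = function(w) {
      # near-separation and non-convergence are recorded on the fit
      # object (see `$warnings`), not clamped away
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$var))[seq_along(beta)]
  se[is.na(beta)] <- NA_real_
  if (any(is.na(beta))) beta[is.na(beta)] <- 0   # aliased columns
  z <- beta / se
  structure(list(beta = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p_value = 2 * pnorm(-abs(z)),
                 loglik = fit$loglik[2], n = fit$n, n_event = fit$nevent,
                 warnings = warn, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (Breslow ties): n=%d, events=%d\n", x$n, x$n_event))
  if (length(x$warnings))
    cat("  fitter warnings:", paste(unique(x$warnings), collapse = "; "), "\n")
  tab <- data.frame(coef = round(x$beta, 3), HR = round(x$hr, 2),
                    lower95 = round(x$ci_lower, 2), upper95 = round(x$ci_upper, 2),
                    p = signif(x$p_value, 3))
  print(tab)
  invisible(x)
}

#' Numerical controls for the penalized Cox path
#'
#' The defaults match the canonical elastic-net software. Simulation
#' studies embedded in the test-suite use a coarser path
#' (`nlambda` 25-30, `lambda_min_ratio` ~0.1, a `pmax` cap) because the
#' permutation machinery refits the whole nested cross-validation
#' hundreds of times.
#'
#' @param nlambda number of lambdas on the log-spaced path.
#' @param lambda_min_ratio smallest lambda as a fraction of the computed
#'   `lambda_max` (`NULL` = software default: 1e-4, or 0.01 when p > n).
#' @param pmax optional cap on the number of predictors ever nonzero
#'   along the path (`NULL` = no cap).
#' @param thresh coordinate-descent convergence threshold.
#' @param maxit maximum passes over the data.
#' @return A list of class `penalized_control`.
#' @export
penalized_control <- function(nlambda = 100, lambda_min_ratio = NULL,
                              pmax = NULL, thresh = 1e-7, maxit = 1e5) {
  structure(list(nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 pmax = pmax, thresh = thresh, maxit = maxit),
            class = "penalized_control")
}

glmnet_args <- function(control, n, p) {
  args <- list(nlambda = control$nlambda, thresh = control$thresh,
               maxit = control$maxit)
  if (!is.null(control$lambda_min_ratio))
    args$lambda.min.ratio <- control$lambda_min_ratio
  if (!is.null(control$pmax)) args$pmax <- min(control$pmax, p + 1)
  args
}

#' Elastic-net penalized Cox regression
#'
#' Fits the regularization path of the Cox model penalized by
#' `lambda * (alpha * ||beta||_1 + (1 - alpha)/2 * ||beta||_2^2)` with
#' Breslow tie handling. Columns are internally centered and scaled for
#' the solver and coefficients reported back on the input scale. At
#' `lambda >= lambda_max` every coefficient is exactly zero.
#'
#' @param X numeric matrix, patients x predictors.
#' @param time,event survival outcome.
#' @param alpha elastic-net mixing parameter (1 = lasso); the pipeline
#'   default is 0.9.
#' @param lambda optional decreasing lambda sequence; `NULL` lets the
#'   solver build its own path from `lambda_max` down.
#' @param control a [penalized_control()] object.
#' @param standardize standardize columns inside the solver.
#' @return An object of class `penalized_cox_fit` wrapping the glmnet
#'   path: `glmnet` (the path object), `alpha`, `lambda` (path),
#'   `lambda_max`, and `beta`/`n_nonzero` at the smallest path lambda.
#'   Use [coef.penalized_cox_fit()] to extract coefficients at any
#'   lambda.
#' @export
fit_penalized_cox <- function(X, time, event, alpha = 0.9, lambda = NULL,
                              control = penalized_control(), standardize = TRUE) {
  X <- as.matrix(X)
  check_outcome(time, event)
  if (nrow(X) != length(time)) stop("rows of `X` must align with the outcome")
  y <- survival::Surv(time, event)
  args <- c(list(x = X, y = y, family = "cox", alpha = alpha,
                 standardize = standardize),
            glmnet_args(control, nrow(X), ncol(X)))
  if (!is.null(lambda)) {
    args$lambda <- sort(lambda, decreasing = TRUE)
    args$nlambda <- NULL
  }
  fit <- suppressWarnings(do.call(glmnet::glmnet, args))
  beta_last <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta_last) <- colnames(X)
  structure(list(glmnet = fit, alpha = alpha, lambda = fit$lambda,
                 lambda_max = max(fit$lambda), beta = beta_last,
                 n_nonzero = sum(beta_last != 0),
                 converged = fit$jerr == 0),
            class = "penalized_cox_fit")
}

#' Coefficients of a penalized Cox fit at a given lambda
#'
#' @param object a `penalized_cox_fit`.
#' @param lambda penalty level; defaults to the smallest on the path.
#' @param exact refit at `lambda` rather than interpolating the path
#'   (needs the training data retained by glmnet).
#' @param ... unused.
#' @return Named coefficient vector on the input scale.
#' @export
coef.penalized_cox_fit <- function(object, lambda = NULL, exact = FALSE, ...) {
  if (is.null(lambda)) return(object$beta)
  b <- as.numeric(coef(object$glmnet, s = lambda, exact = exact))
  names(b) <- rownames(object$glmnet$beta)
  b
}

#' @export
print.penalized_cox_fit <- function(x, ...) {
  cat(sprintf("Elastic-net Cox path: alpha=%.2f, %d lambdas (max %.4g), %d nonzero at path end\n",
              x$alpha, length(x$lambda), x$lambda_max, x$n_nonzero))
  invisible(x)
}

#' Select the penalty by k-fold cross-validated deviance
#'
#' Runs k-fold cross-validation over a log-spaced lambda path and returns
#' the lambda minimizing the mean cross-validated Cox partial-likelihood
#' deviance (Verweij-van Houwelingen formulation). Folds are stratified
#' by event indicator and deterministic given the seed.
#'
#' @param X,time,event design matrix and outcome.
#' @param k number of folds.
#' @param alpha elastic-net mixing parameter.
#' @param seed integer seed for fold assignment.
#' @param control a [penalized_control()].
#' @param foldid optional explicit fold assignment (overrides `k`/`seed`).
#' @return List with `lambda` (the minimizer), `lambda_path`, `cvm`
#'   (mean CV deviance per lambda), `cvsd`, `fit` (a
#'   `penalized_cox_fit` on the full data restricted to the path),
#'   `foldid`, and `deviance_formulation`.
#' @export
select_lambda_cv <- function(X, time, event, k = 5, alpha = 0.9, seed = 1L,
                             control = penalized_control(), foldid = NULL) {
  X <- as.matrix(X)
  check_outcome(time, event)
  if (is.null(foldid)) foldid <- make_folds(event, k = k, seed = seed)
  y <- survival::Surv(time, event)
  args <- c(list(x = X, y = y, family = "cox", alpha = alpha, foldid = foldid,
                 grouped = TRUE),
            glmnet_args(control, nrow(X), ncol(X)))
  cv <- suppressWarnings(do.call(glmnet::cv.glmnet, args))
  fit <- structure(list(glmnet = cv$glmnet.fit, alpha = alpha,
                        lambda = cv$glmnet.fit$lambda,
                        lambda_max = max(cv$glmnet.fit$lambda),
                        beta = {
                          b <- as.numeric(coef(cv, s = "lambda.min"))
                          names(b) <- colnames(X)
                          b
                        },
                        n_nonzero = sum(as.numeric(coef(cv, s = "lambda.min")) != 0),
                        converged = cv$glmnet.fit$jerr == 0),
                   class = "penalized_cox_fit")
  list(lambda = cv$lambda.min, lambda_path = cv$lambda, cvm = cv$cvm,
       cvsd = cv$cvsd, fit = fit, foldid = foldid,
       deviance_formulation = "verweij-van-houwelingen")
}

#' Prognostic index (Cox linear predictor)
#'
#' `x' beta` for new patients; higher values mean higher hazard. For
#' pooled out-of-fold scoring the uncentered linear predictor is used so
#' scores from different training folds share a scale.
#'
#' @param fit a `cox_fit`, `penalized_cox_fit`, or bare coefficient
#'   vector.
#' @param X_new numeric matrix, patients x predictors, columns matching
#'   the fit.
#' @param lambda for penalized fits: lambda at which to take
#'   coefficients (default: smallest on the path).
#' @return Numeric score per patient.
#' @export
prognostic_index <- function(fit, X_new, lambda = NULL) {
  X_new <- as.matrix(X_new)
  beta <- if (inherits(fit, "penalized_cox_fit")) coef(fit, lambda = lambda)
          else if (inherits(fit, "cox_fit")) fit$beta
          else as.numeric(fit)
  if (length(beta) != ncol(X_new))
    stop("`X_new` must have one column per coefficient")
  drop(X_new %*% beta)
}
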