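# Orchestration of the full three-model analysis: preprocessing, model
# fitting, cross-validated evaluation and permutation testing, per miRNA
# type and combined.

#' Configuration for the full analysis pipeline
#'
#' @param counts named list of count matrices or TSV paths, keyed by
#'   miRNA type (e.g. `cf`, `ev`); one or two entries. With two entries
#'   the combined analysis on the intersection of patients is run as
#'   well.
#' @param clinical clinical table (data frame or CSV path) with columns
#'   `patient_id`, `age`, `sex`, `stage`, and — unless `outcome` is given
#'   separately — `dfs_months`, `dfs_event`.
#' @param outcome optional separate outcome table (data frame or CSV
#'   path) with `patient_id`, `dfs_months`, `dfs_event`.
#' @param q3_threshold miRNA count-filter threshold.
#' @param alpha elastic-net mixing parameter.
#' @param k cross-validation folds.
#' @param landmark ROC landmark in months.
#' @param B number of permutations.
#' @param seed master seed.
#' @param permutation which permutation tests to run: `"full"` (per-model
#'   log-rank/AUC nulls), `"added"` (combined vs clinical-only), both
#'   (default) or `"none"`.
#' @param welch use Welch t-tests in the covariate-association screen.
#' @param refold re-draw folds inside full-null permutations.
#' @param control a [penalized_control()].
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(counts, clinical, outcome = NULL, q3_threshold = 5,
                            alpha = 0.9, k = 5, landmark = 24, B = 500,
                            seed = 1L, permutation = c("full", "added"),
                            welch = FALSE, refold = TRUE,
                            control = penalized_control()) {
  if (!is.list(counts) || is.null(names(counts)) || any(names(counts) == ""))
    stop("`counts` must be a named list of matrices or paths")
  if (length(counts) < 1 || length(counts) > 2)
    stop("`counts` must have one or two entries")
  if (landmark <= 0) stop("`landmark` must be positive")
  if (B < 1) stop("`B` must be at least 1")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]")
  if (!all(permutation %in% c("full", "added", "none")))
    stop("`permutation` must be a subset of full/added/none")
  structure(list(counts = counts, clinical = clinical, outcome = outcome,
                 q3_threshold = q3_threshold, alpha = alpha, k = k,
                 landmark = landmark, B = as.integer(B), seed = as.integer(seed),
                 permutation = permutation, welch = isTRUE(welch),
                 refold = isTRUE(refold), control = control),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' File paths in the YAML (under `counts`, `clinical`, `outcome`) are
#' resolved relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  y$counts <- lapply(y$counts, resolve)
  y$clinical <- resolve(y$clinical)
  if (!is.null(y$outcome)) y$outcome <- resolve(y$outcome)
  do.call(analysis_config, y)
}

load_table <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full three-model prognostic analysis
#'
#' Executes, deterministically given the config seed: preprocessing of
#' each count matrix (filters, TMM, Blom); for each miRNA type — and,
#' when two types are supplied, for the combined block on the
#' intersection of patients surviving both filters — fitting of the
#' miRNA-only elastic-net Cox model (Model 1), the combined
#' miRNA + clinical elastic-net model (Model 2) and the clinical-only
#' standard Cox model (Model 3); cross-validated prognostic indices,
#' median-split KM curves and landmark ROC per model; permutation tests
#' of each model's CV log-rank statistic and AUC, and of the added value
#' of Model 2 over Model 3; and the covariate-association screen for
#' sex. In the combined block, miRNA ids are namespaced by type prefix
#' and each matrix keeps its own normalization.
#'
#' @param config an [analysis_config()].
#' @return Object of class `analysis_report`: `descriptives` (per
#'   analysis: n, events, reverse-KM median follow-up, filter tallies),
#'   `analyses` (per analysis: model coefficient tables, CV statistics,
#'   permutation results, ROC/KM coordinates), `associations`, and the
#'   echoed `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  clin <- load_table(config$clinical, read_clinical)
  outc <- if (is.null(config$outcome)) {
    clin[, c("patient_id", "dfs_months", "dfs_event")]
  } else load_table(config$outcome, read.csv)
  counts <- lapply(config$counts, load_table, reader = read_counts)

  prep <- lapply(counts, preprocess_counts, q3_threshold = config$q3_threshold)

  units <- as.list(names(prep))
  if (length(prep) == 2) units <- c(units, list(names(prep)))
  names(units) <- vapply(units, paste, "", collapse = "_")

  analyses <- list()
  for (unit_name in names(units)) {
    types <- units[[unit_name]]
    blocks <- lapply(types, function(ty) {
      m <- t(prep[[ty]]$expression)
      if (length(types) > 1) colnames(m) <- paste0(ty, "_", colnames(m))
      m
    })
    patients <- Reduce(intersect, lapply(blocks, rownames))
    keep <- clin$patient_id[clin$patient_id %in% patients &
                              stats::complete.cases(clin[, c("age", "sex", "stage")])]
    keep <- keep[keep %in% outc$patient_id[!is.na(outc$dfs_months) &
                                             !is.na(outc$dfs_event)]]
    if (length(keep) < 2 * config$k)
      stop("analysis '", unit_name, "': too few aligned patients (", length(keep), ")")
    ci <- clin[match(keep, clin$patient_id), ]
    oi <- outc[match(keep, outc$patient_id), ]
    X_mirna <- do.call(cbind, lapply(blocks, function(b) b[keep, , drop = FALSE]))
    X_clin <- clinical_design(ci)
    time <- oi$dfs_months
    event <- oi$dfs_event
    seed_u <- derive_seed(config$seed, unit_name)

    ## -- full-data model fits (coefficient tables) -----------------------
    sel1 <- select_lambda_cv(X_mirna, time, event, k = config$k,
                             alpha = config$alpha,
                             seed = derive_seed(seed_u, "fit1"),
                             control = config$control)
    sel2 <- select_lambda_cv(cbind(X_clin, X_mirna), time, event, k = config$k,
                             alpha = config$alpha,
                             seed = derive_seed(seed_u, "fit2"),
                             control = config$control)
    m3_fit <- fit_cox(X_clin, time, event)

    ## -- cross-validated evaluation --------------------------------------
    model_X <- list(model1_mirna_only = X_mirna,
                    model2_combined = cbind(X_clin, X_mirna),
                    model3_clinical_only = X_clin)
    fitters <- c(model1_mirna_only = "penalized", model2_combined = "penalized",
                 model3_clinical_only = "standard")
    cv_results <- list()
    perm_results <- list()
    for (mn in names(model_X)) {
      if ("full" %in% config$permutation) {
        pf <- permute_full_null(model_X[[mn]], time, event,
                                fitter = fitters[[mn]], B = config$B,
                                seed = derive_seed(seed_u, "perm", mn),
                                k = config$k, alpha = config$alpha,
                                landmark = config$landmark,
                                control = config$control,
                                refold = config$refold)
        obs <- pf$observed
        perm_results[[mn]] <- pf[c("cv_logrank", "cv_auc")]
      } else {
        obs <- cv_model_statistics(model_X[[mn]], time, event,
                                   fitter = fitters[[mn]], k = config$k,
                                   alpha = config$alpha,
                                   landmark = config$landmark,
                                   seed = derive_seed(seed_u, "perm", mn, "obs"),
                                   control = config$control, keep_cvpi = TRUE)
      }
      roc <- cv_landmark_roc(obs$cvpi$scores$score, time, event,
                             landmark = config$landmark)
      km <- cv_km_logrank(obs$cvpi, time, event)
      cv_results[[mn]] <- list(logrank = obs$logrank, auc = obs$auc,
                               cvpi = obs$cvpi, roc = roc, km = km$curves)
    }
    added <- NULL
    if ("added" %in% config$permutation) {
      added <- added_value_test(X_clin, X_mirna, time, event, B = config$B,
                                seed = derive_seed(seed_u, "added"),
                                k = config$k, alpha = config$alpha,
                                landmark = config$landmark,
                                control = config$control)
    }

    nz <- function(beta) beta[beta != 0]
    analyses[[unit_name]] <- list(
      n = length(keep), n_events = sum(event),
      median_followup = reverse_km_median_followup(time, event),
      patients = keep,
      preprocessing = lapply(prep[types], function(p) p$provenance),
      model1 = list(coefficients = nz(sel1$fit$beta), lambda = sel1$lambda,
                    n_selected = sum(sel1$fit$beta != 0)),
      model2 = list(coefficients = nz(sel2$fit$beta), lambda = sel2$lambda,
                    n_selected = sum(sel2$fit$beta != 0)),
      model3 = list(coefficients = m3_fit$beta, hr = m3_fit$hr,
                    ci_lower = m3_fit$ci_lower, ci_upper = m3_fit$ci_upper,
                    p_value = m3_fit$p_value),
      cv = cv_results, permutation = perm_results, added_value = added)
  }

  associations <- lapply(prep, function(p) {
    idx <- match(colnames(p$expression), clin$patient_id)
    ok <- !is.na(idx) & !is.na(clin$sex[idx])
    if (sum(ok) < 4) return(NULL)
    mirna_covariate_ttests(p$expression[, ok, drop = FALSE],
                           clin$sex[idx[ok]], welch = config$welch)
  })

  structure(list(descriptives = lapply(analyses, function(a)
                   list(n = a$n, n_events = a$n_events,
                        median_followup = a$median_followup)),
                 analyses = analyses, associations = associations,
                 config = config),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Prognostic miRNA signature analysis report\n")
  for (unit in names(x$analyses)) {
    a <- x$analyses[[unit]]
    cat(sprintf("\n== %s: n=%d, events=%d, median follow-up=%s months ==\n",
                unit, a$n, a$n_events,
                if (is.na(a$median_followup)) "NR"
                else sprintf("%.1f", a$median_followup)))
    cat(sprintf("  Model 1 (miRNA only): %d miRNAs selected; CV AUC=%.3f, CV log-rank=%.2f\n",
                a$model1$n_selected, a$cv$model1_mirna_only$auc,
                a$cv$model1_mirna_only$logrank))
    cat(sprintf("  Model 2 (combined):   %d predictors selected; CV AUC=%.3f, CV log-rank=%.2f\n",
                a$model2$n_selected, a$cv$model2_combined$auc,
                a$cv$model2_combined$logrank))
    cat(sprintf("  Model 3 (clinical):   CV AUC=%.3f, CV log-rank=%.2f\n",
                a$cv$model3_clinical_only$auc, a$cv$model3_clinical_only$logrank))
    if (length(a$permutation)) {
      for (mn in names(a$permutation)) {
        pr <- a$permutation[[mn]]
        cat(sprintf("  %s permutation p: log-rank %.3f, AUC %.3f\n", mn,
                    pr$cv_logrank$p_value, pr$cv_auc$p_value))
      }
    }
    if (!is.null(a$added_value)) {
      cat(sprintf("  added value (Model 2 vs 3, shared-fold run): delta log-rank %.2f (p=%.3f), delta AUC %.3f (p=%.3f)\n",
                  a$added_value$delta_logrank$observed,
                  a$added_value$delta_logrank$p_value,
                  a$added_value$delta_auc$observed,
                  a$added_value$delta_auc$p_value))
    }
  }
  invisible(x)
}

#' Write an analysis report to JSON and TSV
#'
#' Emits `report.json` (all statistics, coefficients and permutation
#' p-values, with full null draws for audit) and, per analysis, a
#' coefficient table `<analysis>_coefficients.tsv` with one row per
#' predictor and one column per model.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  slim <- lapply(report$analyses, function(a) {
    list(n = a$n, n_events = a$n_events, median_followup = a$median_followup,
         model1 = a$model1, model2 = a$model2, model3 = a$model3,
         cv = lapply(a$cv, function(cv) list(logrank = cv$logrank, auc = cv$auc)),
         permutation = lapply(a$permutation, function(p)
           lapply(p, function(r) r[c("statistic_name", "observed", "p_value",
                                     "B", "null_draws")])),
         added_value = if (is.null(a$added_value)) NULL else
           lapply(a$added_value[c("delta_logrank", "delta_auc")], function(r)
             r[c("statistic_name", "observed", "p_value", "B", "null_draws")]))
  })
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(list(analyses = slim,
                            seed = report$config$seed,
                            B = report$config$B,
                            landmark = report$config$landmark,
                            alpha = report$config$alpha),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  for (unit in names(report$analyses)) {
    a <- report$analyses[[unit]]
    preds <- unique(c(names(a$model1$coefficients), names(a$model2$coefficients),
                      names(a$model3$coefficients)))
    tab <- data.frame(predictor = preds,
                      model1 = a$model1$coefficients[preds],
                      model2 = a$model2$coefficients[preds],
                      model3 = a$model3$coefficients[preds],
                      hr_model3 = a$model3$hr[preds],
                      p_model3 = a$model3$p_value[preds],
                      row.names = NULL, check.names = FALSE)
    write.table(tab, file.path(dir, paste0(unit, "_coefficients.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(json_path)
}
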