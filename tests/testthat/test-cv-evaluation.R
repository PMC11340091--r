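test_that("fold assignment is balanced, event-stratified and deterministic", {
  event <- rep(c(1, 0), c(4, 6))
  f <- make_folds(event, k = 5, seed = 3)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(f, make_folds(event, k = 5, seed = 3))
  expect_false(identical(f, make_folds(event, k = 5, seed = 4)))
  # event counts per fold differ by at most one
  for (rep in 1:10) {
    ev <- withr::with_seed(rep, rbinom(83, 1, 0.3))
    ff <- make_folds(ev, k = 5, seed = rep)
    per_fold <- table(factor(ff, levels = 1:5), ev)[, "1"]
    expect_lte(diff(range(per_fold)), 1)
    expect_lte(diff(range(table(ff))), 1)
  }
})

test_that("model specifications pin the fitter to the predictor blocks", {
  expect_equal(model_spec("model3_clinical_only")$fitter, "standard")
  expect_equal(model_spec("model1_mirna_only")$fitter, "penalized")
  expect_equal(model_spec("model2_combined")$blocks, c("clinical", "mirna"))
})

test_that("out-of-fold scores come from models never trained on the patient", {
  # corrupting one patient's outcome must leave the scores of that
  # patient's entire fold untouched (their model excludes the fold), and
  # may only change other folds' scores
  co <- simulate_cohort(simulation_config(n_patients = 60, n_mirnas = 120,
                                          n_prognostic = 3, seed = 31))
  d <- cohort_design(co)
  folds <- make_folds(d$event, k = 5, seed = 7)
  cv1 <- cv_prognostic_indices(d$Xm, d$time, d$event, "penalized", folds,
                               seed = 11, control = fast_control())
  i <- 1L
  time2 <- d$time; event2 <- d$event
  time2[i] <- 1; event2[i] <- 1 - event2[i]
  cv2 <- cv_prognostic_indices(d$Xm, time2, event2, "penalized", folds,
                               seed = 11, control = fast_control())
  own_fold <- folds == folds[i]
  expect_equal(cv1$scores$score[own_fold], cv2$scores$score[own_fold],
               tolerance = 1e-12)
})

test_that("clinical-only CV enriches the high-risk group in advanced stage", {
  cfg <- simulation_config(n_patients = 160, n_mirnas = 40, n_prognostic = 0,
                           clinical_effects = c(stage_ii = 1.0, stage_iiia = 1.6,
                                                sex_m = 0, age = 0),
                           seed = 29)
  co <- simulate_cohort(cfg)
  d <- cohort_design(co)
  folds <- make_folds(d$event, k = 5, seed = 5)
  cvpi <- cv_prognostic_indices(d$Xc, d$time, d$event, "standard", folds,
                                seed = 5)
  frac_iiia <- tapply(d$clinical$stage == "IIIA", cvpi$scores$group, mean)
  expect_gt(frac_iiia[["high"]], frac_iiia[["low"]])
})

test_that("duplicated clinical columns leave model-3 scores and groups unchanged", {
  co <- simulate_cohort(simulation_config(n_patients = 80, n_mirnas = 30,
                                          n_prognostic = 0, seed = 41))
  d <- cohort_design(co)
  folds <- make_folds(d$event, k = 5, seed = 2)
  base <- cv_prognostic_indices(d$Xc, d$time, d$event, "standard", folds, seed = 3)
  dup <- cv_prognostic_indices(cbind(d$Xc, d$Xc), d$time, d$event, "standard",
                               folds, seed = 3)
  expect_equal(dup$scores$score, base$scores$score, tolerance = 1e-6)
  expect_identical(dup$scores$group, base$scores$group)
})

test_that("risk groups partition patients at the pooled out-of-fold median", {
  co <- simulate_cohort(simulation_config(n_patients = 50, n_mirnas = 60,
                                          n_prognostic = 2, seed = 13))
  d <- cohort_design(co)
  folds <- make_folds(d$event, k = 5, seed = 1)
  cvpi <- cv_prognostic_indices(d$Xm, d$time, d$event, "penalized", folds,
                                seed = 1, control = fast_control())
  s <- cvpi$scores
  expect_equal(sort(unique(s$fold)), 1:5)
  expect_identical(s$group, ifelse(s$score > median(s$score), "high", "low"))
  swap <- logrank_test(d$time, d$event, s$group)
  swapped <- logrank_test(d$time, d$event,
                          ifelse(s$group == "high", "low", "high"))
  expect_equal(swap$statistic, swapped$statistic, tolerance = 1e-12)
})

test_that("landmark ROC matches closed forms and the IPCW concordance oracle", {
  # perfect separation without censoring before the landmark
  time <- c(5, 10, 15, 30, 40, 50); event <- c(1, 1, 1, 0, 0, 0)
  roc <- cv_landmark_roc(c(3, 2.5, 2, 1, 0.5, 0), time, event, landmark = 24)
  expect_equal(roc$auc, 1)
  expect_equal(roc$fp[1], 0); expect_equal(roc$tp[1], 0)
  expect_equal(roc$fp[length(roc$fp)], 1)
  expect_equal(roc$tp[length(roc$tp)], 1)
  # 8-patient toy with one censored record against the pairwise oracle
  time8 <- c(4, 9, 12, 18, 20, 30, 36, 40)
  event8 <- c(1, 1, 0, 1, 1, 0, 0, 0)
  s8 <- c(2.0, 1.1, 0.4, 1.7, -0.2, 0.8, -1.0, 0.3)
  roc8 <- cv_landmark_roc(s8, time8, event8, landmark = 24)
  expect_equal(roc8$auc, ipcw_auc_oracle(s8, time8, event8, 24),
               tolerance = 1e-12)
  expect_equal(roc8$n_cases, 4)
  expect_equal(roc8$n_controls, 3)
  # monotone curve
  expect_true(all(diff(roc8$fp) >= 0))
  expect_true(all(diff(roc8$tp) >= 0))
})

test_that("AUC is invariant to monotone score transforms and flips under negation", {
  withr::with_seed(47, {
    n <- 60
    s <- rnorm(n)
    time <- rexp(n, 0.05 * exp(0.5 * s))
    event <- rbinom(n, 1, 0.8)
  })
  time <- pmax(time, 0.1)
  a <- cv_landmark_roc(s, time, event, 24)$auc
  expect_equal(cv_landmark_roc(2 * s + 7, time, event, 24)$auc, a,
               tolerance = 1e-12)
  expect_equal(cv_landmark_roc(exp(s), time, event, 24)$auc, a, tolerance = 1e-12)
  expect_equal(cv_landmark_roc(-s, time, event, 24)$auc, 1 - a, tolerance = 1e-12)
})

test_that("uninformative scores give AUC near one half without censoring", {
  withr::with_seed(53, {
    n <- 2000
    s <- rnorm(n)
    time <- rexp(n, 1 / 30)
  })
  event <- rep(1, n)
  a <- cv_landmark_roc(s, time, event, 24)$auc
  expect_lt(abs(a - 0.5), 0.04)
})

test_that("degenerate landmark configurations error clearly", {
  expect_error(cv_landmark_roc(1:3, c(30, 40, 50), c(0, 0, 0), 24), "no cases")
  expect_error(cv_landmark_roc(1:3, c(5, 10, 12), c(1, 1, 1), 24), "no controls")
})
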