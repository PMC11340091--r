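test_that("Kaplan-Meier estimate matches closed forms and hand calculation", {
  # all censored: flat at 1, median not reached
  km <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km$all$surv == 1))
  expect_true(is.na(km$all$median))
  # three events, no censoring
  km2 <- km_estimate(1:3, c(1, 1, 1))
  expect_equal(km2$all$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # mixed toy: events at 2 and 4, censorings at 3, 5, 6
  time <- c(2, 3, 4, 5, 6); event <- c(1, 0, 1, 0, 0)
  km3 <- km_estimate(time, event)
  oracle <- hand_km(time, event)
  expect_equal(km3$all$surv[km3$all$n_event > 0], oracle$surv, tolerance = 1e-12)
  expect_equal(oracle$surv, c(4 / 5, 4 / 5 * 2 / 3), tolerance = 1e-12)
  # survival is non-increasing from 1 and events feed the log-rank input
  expect_true(all(diff(km3$all$surv) <= 0))
  expect_equal(sum(km3$all$n_event), sum(event))
})

test_that("log-rank test matches a brute-force observed-minus-expected oracle", {
  # duplicated data in two groups: exactly no difference
  time <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(time, event, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  # random two-group data, including non-overlapping event times
  for (rep in 1:10) {
    withr::with_seed(rep + 40, {
      n <- 30
      tt <- round(rexp(n, 0.1), 2) + 0.01
      ev <- rbinom(n, 1, 0.7)
      gg <- rep(1:2, length.out = n)
    })
    expect_equal(logrank_test(tt, ev, gg)$statistic,
                 brute_logrank(tt, ev, gg), tolerance = 1e-8)
  }
  t2 <- c(1, 2, 3, 11, 12, 13); e2 <- rep(1, 6); g2 <- rep(1:2, each = 3)
  expect_equal(logrank_test(t2, e2, g2)$statistic, brute_logrank(t2, e2, g2),
               tolerance = 1e-10)
  # degenerate single group
  expect_equal(logrank_test(t2, e2, rep(1, 6))$statistic, 0)
})

test_that("permuted log-rank statistics average near their degrees of freedom", {
  withr::with_seed(7, {
    n <- 60
    tt <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.6); gg <- rep(1:2, each = 30)
    stats <- replicate(400, logrank_test(tt, ev, sample(gg))$statistic)
  })
  expect_lt(abs(mean(stats) - 1), 0.3)
})

test_that("reverse Kaplan-Meier follow-up behaves at the extremes and on a toy", {
  expect_true(is.na(reverse_km_median_followup(c(1, 2, 3), c(1, 1, 1))))
  # no events: reduces to the median observation time
  expect_equal(reverse_km_median_followup(c(2, 5, 9), c(0, 0, 0)), 5)
  # toy with a real event: event times are censored observations of follow-up
  time <- c(10, 20, 30, 40, 50); event <- c(0, 0, 1, 0, 0)
  # reverse KM "events" at 10, 20, 40, 50 with the true event censored at 30:
  # S = 4/5 at 10, 3/5 at 20, 3/10 at 40 -> median follow-up 40
  expect_equal(reverse_km_median_followup(time, event), 40)
})

test_that("Cox fit maximizes the Breslow partial likelihood", {
  # 10-patient single-covariate toy against a grid-search maximizer
  withr::with_seed(11, {
    x <- rnorm(10)
    tt <- rexp(10, exp(0.8 * x))
    ev <- rbinom(10, 1, 0.8)
  })
  ev[1] <- 1
  fit <- fit_cox(cbind(x = x), tt, ev)
  beta_grid <- grid_cox(x, tt, ev, step = 1e-3)
  expect_equal(unname(fit$beta), beta_grid, tolerance = 2e-3)
  # exchangeable outcomes across a balanced binary covariate: beta = 0
  t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(1, 8); x2 <- rep(0:1, each = 4)
  fit2 <- fit_cox(cbind(z = c(x2)), c(t2), c(e2))
  expect_equal(unname(fit2$beta), 0, tolerance = 1e-8)
  # duplicating every record leaves the estimate unchanged
  fit3 <- fit_cox(cbind(x = rep(x, 2)), rep(tt, 2), rep(ev, 2))
  expect_equal(fit3$beta, fit$beta, tolerance = 1e-6)
  # CI brackets the hazard ratio
  expect_true(all(fit$ci_lower <= fit$hr & fit$hr <= fit$ci_upper))
  expect_error(fit_cox(cbind(k = rep(1, 10)), tt, ev), "constant")
})

test_that("penalized Cox fit has the stated limiting behaviour", {
  withr::with_seed(13, {
    n <- 50
    X <- cbind(a = rnorm(n), b = rnorm(n))
    tt <- rexp(n, exp(0.6 * X[, 1] - 0.4 * X[, 2]))
    ev <- rbinom(n, 1, 0.8)
  })
  fit <- fit_penalized_cox(X, tt, ev, alpha = 0.9)
  # at and above lambda_max every coefficient is exactly zero
  expect_equal(unname(coef(fit, lambda = fit$lambda_max)), c(0, 0))
  expect_equal(unname(coef(fit, lambda = fit$lambda_max * 2)), c(0, 0))
  # lambda -> 0 recovers the unpenalized fit
  lam <- fit$lambda_max * c(1, 0.5, 0.1, 0.01, 0.001, 1e-4, 1e-5)
  fit0 <- fit_penalized_cox(X, tt, ev, alpha = 0.9, lambda = lam,
                            control = penalized_control(thresh = 1e-12))
  mle <- fit_cox(X, tt, ev)
  expect_equal(unname(fit0$beta), unname(mle$beta), tolerance = 1e-3)
})

test_that("penalized solution is locally optimal for the elastic-net objective", {
  withr::with_seed(19, {
    n <- 100; p <- 5
    X <- scale(matrix(rnorm(n * p), n, p))
    colnames(X) <- paste0("v", 1:p)
    tt <- rexp(n, exp(0.8 * X[, 1] - 0.5 * X[, 2]))
    ev <- as.numeric(tt <= quantile(tt, 0.7))
    tt <- pmin(tt, quantile(tt, 0.7))
  })
  alpha <- 0.9; lam <- 0.05
  fit <- fit_penalized_cox(X, tt, ev, alpha = alpha, lambda = c(0.3, 0.1, lam),
                           control = penalized_control(thresh = 1e-14),
                           standardize = FALSE)
  b <- coef(fit, lambda = lam)
  objective <- function(beta) {
    eta <- drop(X %*% beta)
    nll <- -sum(vapply(which(ev == 1), function(i)
      eta[i] - log(sum(exp(eta[tt >= tt[i]]))), 0))
    nll / n + lam * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
  }
  obj_hat <- objective(b)
  perturbed <- withr::with_seed(20, replicate(10000, objective(b + rnorm(p, 0, 1e-3))))
  expect_true(all(obj_hat <= perturbed + 1e-12))
})

test_that("penalized fits never exceed the unpenalized l1 norm", {
  for (rep in 1:5) {
    withr::with_seed(rep + 60, {
      n <- 60
      X <- cbind(rnorm(n), rnorm(n), rnorm(n))
      colnames(X) <- paste0("x", 1:3)
      tt <- rexp(n, exp(0.5 * X[, 1]))
      ev <- rbinom(n, 1, 0.7)
    })
    mle <- fit_cox(X, tt, ev)
    fit <- fit_penalized_cox(X, tt, ev, alpha = 0.9)
    l1 <- apply(abs(fit$glmnet$beta), 2, sum)
    expect_true(all(l1 <= sum(abs(mle$beta)) + 1e-6))
  }
})

test_that("cross-validated lambda selection is deterministic and finds strong predictors", {
  withr::with_seed(23, {
    n <- 120; p <- 20
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
    tt <- rexp(n, exp(1.2 * X[, 7]))
    ev <- as.numeric(tt <= quantile(tt, 0.6))
    tt <- pmin(tt, quantile(tt, 0.6))
  })
  s1 <- select_lambda_cv(X, tt, ev, seed = 99, control = fast_control())
  s2 <- select_lambda_cv(X, tt, ev, seed = 99, control = fast_control())
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$foldid, s2$foldid)
  expect_true(s1$fit$beta["m7"] != 0)
  expect_gt(s1$fit$beta["m7"], 0)
})

test_that("prognostic index is the linear predictor", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(prognostic_index(c(0, 0), X), rep(0, 3))
  expect_equal(prognostic_index(c(2, 0), X), c(2, 4, 6))
  expect_equal(prognostic_index(c(0.5, -1), X), 0.5 * X[, 1] - X[, 2])
})
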