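# Independent reference implementations used as oracles. These are
# deliberately written from first principles (sorting, enumeration,
# explicit sums) and never call the code paths they check.

# Linear-interpolation quantile of order statistics, by explicit sorting.
brute_quantile <- function(x, p) {
  s <- unname(sort(x))
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# Reference TMM: pairwise trimmed, variance-weighted mean of M-values
# against the sample whose upper count quartile (per total) is closest
# to the mean, factors rescaled to geometric mean 1.
ref_tmm <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) brute_quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    keep <- obs > 0 & rf > 0
    obs <- obs[keep]; rf <- rf[keep]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    nn <- length(M)
    loL <- floor(nn * logratio_trim) + 1; hiL <- nn + 1 - loL
    loS <- floor(nn * abs_trim) + 1; hiS <- nn + 1 - loS
    keep2 <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, 0)
  f / exp(mean(log(f)))
}

# Product-limit estimator by explicit looping over distinct event times.
hand_km <- function(time, event) {
  tj <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tj))
  for (i in seq_along(tj)) {
    at_risk <- sum(time >= tj[i])
    d <- sum(time == tj[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = tj, surv = surv)
}

# Two-group log-rank chi-square by explicit observed-minus-expected
# summation over distinct event times (hypergeometric variance).
brute_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  tj <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in tj) {
    n1 <- sum(time >= t & g == 1)
    n2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Explicit Breslow log partial likelihood for a single-column design.
breslow_lpl <- function(beta, x, time, event) {
  eta <- x * beta
  sum(vapply(which(event == 1), function(i)
    eta[i] - log(sum(exp(eta[time >= time[i]]))), 0))
}

# Grid-search maximizer of the Breslow partial likelihood (single
# covariate; evaluation vectorized over the grid, still exhaustive).
grid_cox <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  E <- exp(outer(x, grid))
  ll <- numeric(length(grid))
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    ll <- ll + x[i] * grid - log(colSums(E[rs, , drop = FALSE]))
  }
  grid[which.max(ll)]
}

# IPCW weighted concordance between cases and controls at a landmark,
# with ties counted 1/2 (pairwise double sum; censoring survival by an
# explicit reverse product-limit loop).
ipcw_auc_oracle <- function(scores, time, event, landmark) {
  ckm <- hand_km(time, 1 - event)   # censoring "events"
  G <- function(t, strict) {
    keep <- if (strict) ckm$time < t else ckm$time <= t
    if (!any(keep)) 1 else min(ckm$surv[keep])
  }
  cases <- which(event == 1 & time <= landmark)
  controls <- which(time > landmark)
  w_case <- vapply(time[cases], function(t) 1 / G(t, strict = TRUE), 0)
  w_ctrl <- rep(1 / G(landmark, strict = FALSE), length(controls))
  num <- 0
  for (i in seq_along(cases)) for (j in seq_along(controls)) {
    si <- scores[cases[i]]; sj <- scores[controls[j]]
    conc <- if (si > sj) 1 else if (si == sj) 0.5 else 0
    num <- num + w_case[i] * w_ctrl[j] * conc
  }
  num / (sum(w_case) * sum(w_ctrl))
}

# Preprocess a synthetic cohort and align design matrices to outcome.
cohort_design <- function(cohort, q3_threshold = 5) {
  prep <- preprocess_counts(cohort$counts, q3_threshold = q3_threshold)
  Xm <- t(prep$expression)
  ids <- rownames(Xm)
  oi <- cohort$outcome[match(ids, cohort$outcome$patient_id), ]
  ci <- cohort$clinical[match(ids, cohort$clinical$patient_id), ]
  list(Xm = Xm, Xc = clinical_design(ci), time = oi$dfs_months,
       event = oi$dfs_event, clinical = ci, prep = prep)
}

# Coarse-path solver settings shared by the simulation-heavy tests.
fast_control <- function() penalized_control(nlambda = 30, lambda_min_ratio = 0.1,
                                             pmax = 60)
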