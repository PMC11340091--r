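#' Configuration for the synthetic miRNA-seq survival cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults emulate a resected early-stage NSCLC surveillance cohort:
#' roughly 200 patients, 2,000 profiled miRNAs of which most are
#' structurally low-abundance (so that 200-450 survive the third-quartile
#' count filter), a 25-35% disease-free-survival event fraction over a
#' 36-month administrative follow-up window, and clinical log-hazard
#' ratios of the magnitude reported for pathological stage (HR ~ 2.5-4.5
#' vs stage I), sex and age in resected NSCLC.
#'
#' @param n_patients number of patients.
#' @param n_mirnas number of profiled miRNAs (pre-filter).
#' @param n_prognostic number of truly prognostic miRNAs.
#' @param effect_sizes log-hazard ratio per prognostic miRNA, on the
#'   standardized latent-expression scale (comparable to coefficients of a
#'   Cox model fitted to inverse-normal-transformed expression). Length
#'   must equal `n_prognostic`.
#' @param clinical_effects named numeric vector of log-hazard ratios:
#'   `stage_ii` and `stage_iiia` (vs stage I), `sex_m` (M vs F), `age`
#'   (per year).
#' @param stage_probs probabilities of pathological stage I, II, IIIA;
#'   must sum to 1.
#' @param baseline_shape,baseline_scale Weibull baseline hazard shape and
#'   scale (months) for a stage-I female patient of mean age.
#' @param censor_admin_max administrative censoring time in months.
#' @param censor_uniform_max upper bound of an independent uniform dropout
#'   time; `Inf` (default) disables random dropout so censoring is purely
#'   administrative.
#' @param nb_dispersion negative-binomial dispersion of counts given the
#'   latent expression (variance = mu + dispersion * mu^2); 0 gives
#'   Poisson counts.
#' @param mean_log_expression length-2 vector `c(mean, sd)` of the
#'   natural-log relative-abundance distribution of expressed miRNAs.
#' @param latent_sd standard deviation of the per-patient latent
#'   log-expression fluctuation around each miRNA's mean (biological
#'   variation; the prognostic signal lives on this component).
#' @param libsize_log_mean,libsize_log_sd log-normal library size
#'   parameters (natural log of total counts per sample).
#' @param zero_fraction fraction of miRNAs drawn from the structurally
#'   low-abundance component (these are what the Q3 < 5 filter removes).
#' @param confound_with_stage if `TRUE`, the prognostic miRNAs' latent
#'   expression is a deterministic function of pathological stage and the
#'   hazard depends on stage only: the miRNA block then carries no
#'   information beyond the clinical factors (negative control for
#'   added-value testing).
#' @param seed master integer seed; every sub-draw uses a stream derived
#'   from it.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_patients = 200,
                              n_mirnas = 2000,
                              n_prognostic = 5,
                              effect_sizes = rep_len(c(0.7, -0.7), n_prognostic),
                              clinical_effects = c(stage_ii = 1.0, stage_iiia = 1.45,
                                                   sex_m = 0.27, age = 0.025),
                              stage_probs = c(0.645, 0.170, 0.185),
                              baseline_shape = 1.2,
                              baseline_scale = 180,
                              censor_admin_max = 36,
                              censor_uniform_max = Inf,
                              nb_dispersion = 0.2,
                              mean_log_expression = c(mean = 0, sd = 2),
                              latent_sd = 0.8,
                              libsize_log_mean = log(1e6),
                              libsize_log_sd = 0.4,
                              zero_fraction = 0.85,
                              confound_with_stage = FALSE,
                              seed = 1L) {
  if (n_prognostic == 0) effect_sizes <- numeric(0)
  cfg <- list(n_patients = as.integer(n_patients),
              n_mirnas = as.integer(n_mirnas),
              n_prognostic = as.integer(n_prognostic),
              effect_sizes = as.numeric(effect_sizes),
              clinical_effects = clinical_effects,
              stage_probs = as.numeric(stage_probs),
              baseline_shape = baseline_shape,
              baseline_scale = baseline_scale,
              censor_admin_max = censor_admin_max,
              censor_uniform_max = censor_uniform_max,
              nb_dispersion = nb_dispersion,
              mean_log_expression = as.numeric(mean_log_expression),
              latent_sd = latent_sd,
              libsize_log_mean = libsize_log_mean,
              libsize_log_sd = libsize_log_sd,
              zero_fraction = zero_fraction,
              confound_with_stage = isTRUE(confound_with_stage),
              age_center = 69,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_mirnas >= 1, cfg$n_prognostic >= 0)
  if (cfg$n_prognostic > cfg$n_mirnas)
    stop("`n_prognostic` cannot exceed `n_mirnas`")
  if (length(cfg$effect_sizes) != cfg$n_prognostic)
    stop("`effect_sizes` must have length `n_prognostic`")
  req <- c("stage_ii", "stage_iiia", "sex_m", "age")
  if (!all(req %in% names(cfg$clinical_effects)))
    stop("`clinical_effects` must be named: ", paste(req, collapse = ", "))
  if (length(cfg$stage_probs) != 3 || abs(sum(cfg$stage_probs) - 1) > 1e-8)
    stop("`stage_probs` must be a 3-vector summing to 1")
  if (cfg$baseline_shape <= 0 || cfg$baseline_scale <= 0)
    stop("Weibull baseline shape and scale must be strictly positive")
  if (cfg$censor_admin_max <= 0) stop("`censor_admin_max` must be positive")
  if (cfg$nb_dispersion < 0) stop("`nb_dispersion` must be non-negative")
  if (cfg$latent_sd < 0) stop("`latent_sd` must be non-negative")
  if (cfg$zero_fraction < 0 || cfg$zero_fraction >= 1)
    stop("`zero_fraction` must be in [0, 1)")
  if (length(cfg$mean_log_expression) != 2 || cfg$mean_log_expression[2] <= 0)
    stop("`mean_log_expression` must be c(mean, sd) with sd > 0")
  invisible(cfg)
}

#' Simulate a synthetic miRNA-seq cohort with survival outcomes
#'
#' Generates a cohort carrying the statistical structure the downstream
#' analysis assumes: negative-binomial miRNA counts with log-normal
#' library sizes on top of a latent log-expression surface, and
#' disease-free-survival times drawn from a Weibull-baseline proportional
#' hazards model whose linear predictor combines clinical covariates and
#' the standardized latent expression of the prognostic miRNAs.
#'
#' Generative steps, in order:
#' 1. Clinical covariates: stage ~ `stage_probs`, sex (60% male), age ~
#'    Normal(69, 8) truncated to 44-85 years.
#' 2. Latent expression: each miRNA gets a mean log relative abundance
#'    from a two-component mixture (expressed vs structurally low, 8
#'    natural-log units lower); per patient, a standardized latent
#'    fluctuation `u ~ N(0, 1)` scaled by `latent_sd` is added.
#'    Prognostic miRNAs are drawn from the upper part of the expressed
#'    component so they reliably survive count filtering.
#' 3. Hazard: `lp = sum(effect_sizes * u_prognostic) + clinical effects`
#'    (age centered at 69). Under `confound_with_stage` the prognostic
#'    miRNAs' `u` is the standardized stage score itself and the hazard
#'    uses the clinical effects only.
#' 4. Event times by Weibull inversion: `T = scale * (-log(U)/exp(lp))^(1/shape)`;
#'    censoring time `C = min(censor_admin_max, Uniform(0, censor_uniform_max))`;
#'    observed time `min(T, C)`, event indicator `T <= C`.
#' 5. Counts: per-sample relative abundances are the softmax of the
#'    latent log-expression; `counts ~ NB(mu = libsize * abundance,
#'    dispersion)`.
#'
#' The same configuration (including its seed) always yields a
#' bit-identical cohort.
#'
#' @param config a [simulation_config()] object.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `counts` (integer matrix, miRNAs x samples), `clinical` (data frame:
#'   `patient_id`, `age`, `sex`, `stage`), `outcome` (data frame:
#'   `patient_id`, `dfs_months`, `dfs_event`), `truth` (prognostic miRNA
#'   ids, effect sizes, per-patient true linear predictor and its
#'   components) and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_patients = 40, n_mirnas = 100,
#'                                             n_prognostic = 2, seed = 7))
#' dim(cohort$counts)
#' table(cohort$outcome$dfs_event)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  n <- config$n_patients
  p <- config$n_mirnas
  ids <- sprintf("P%03d", seq_len(n))
  mirna_ids <- sprintf("mir%04d", seq_len(p))

  ## -- clinical covariates ------------------------------------------------
  clin <- withr::with_seed(derive_seed(config$seed, "clinical"), {
    stage <- sample(c("I", "II", "IIIA"), n, replace = TRUE, prob = config$stage_probs)
    sex <- ifelse(runif(n) < 0.6, "M", "F")
    age <- round(pmin(pmax(rnorm(n, 69, 8), 44), 85))
    data.frame(patient_id = ids, age = age, sex = sex, stage = stage,
               stringsAsFactors = FALSE)
  })
  stage_num <- match(clin$stage, c("I", "II", "IIIA"))

  ## -- latent expression surface ------------------------------------------
  mu_mean <- config$mean_log_expression[1]
  mu_sd <- config$mean_log_expression[2]
  n_low <- round(config$zero_fraction * p)
  expr <- withr::with_seed(derive_seed(config$seed, "expression"), {
    low <- rep(FALSE, p)
    if (n_low > 0) low[sample.int(p, n_low)] <- TRUE
    m_g <- numeric(p)
    m_g[!low] <- rnorm(sum(!low), mu_mean, mu_sd)
    m_g[low] <- rnorm(n_low, mu_mean - 8, 1)
    prog <- integer(0)
    if (config$n_prognostic > 0) {
      candidates <- which(!low)
      if (length(candidates) < config$n_prognostic)
        stop("too few expressed miRNAs to host the prognostic set; lower `zero_fraction`")
      prog <- sort(sample(candidates, config$n_prognostic))
      # prognostic miRNAs sit in the upper expressed range so they are not
      # removed by the count filter before the signal can be recovered
      m_g[prog] <- rnorm(config$n_prognostic, mu_mean + 1, 1)
    }
    u <- matrix(rnorm(p * n), nrow = p, ncol = n)   # standardized latent
    list(m_g = m_g, u = u, prog = prog)
  })
  u <- expr$u
  if (config$confound_with_stage && config$n_prognostic > 0) {
    ss <- (stage_num - mean(stage_num)) / max(sd(stage_num), 1e-12)
    u[expr$prog, ] <- matrix(rep(ss, each = config$n_prognostic),
                             nrow = config$n_prognostic)
  }

  ## -- hazard and survival -------------------------------------------------
  ce <- config$clinical_effects
  lp_clin <- ce[["stage_ii"]] * (stage_num == 2) +
    ce[["stage_iiia"]] * (stage_num == 3) +
    ce[["sex_m"]] * (clin$sex == "M") +
    ce[["age"]] * (clin$age - config$age_center)
  lp_mirna <- if (config$n_prognostic > 0 && !config$confound_with_stage) {
    drop(crossprod(u[expr$prog, , drop = FALSE], config$effect_sizes))
  } else rep(0, n)
  lp <- lp_clin + lp_mirna

  surv <- withr::with_seed(derive_seed(config$seed, "survival"), {
    tt <- config$baseline_scale * (-log(runif(n)) / exp(lp))^(1 / config$baseline_shape)
    cens <- rep(config$censor_admin_max, n)
    if (is.finite(config$censor_uniform_max))
      cens <- pmin(cens, runif(n, 0, config$censor_uniform_max))
    time <- pmax(pmin(tt, cens), 1e-4)
    data.frame(patient_id = ids, dfs_months = time,
               dfs_event = as.integer(tt <= cens), stringsAsFactors = FALSE)
  })

  ## -- counts ---------------------------------------------------------------
  counts <- withr::with_seed(derive_seed(config$seed, "counts"), {
    lib <- exp(rnorm(n, config$libsize_log_mean, config$libsize_log_sd))
    z <- expr$m_g + config$latent_sd * u            # p x n latent log-expression
    rel <- exp(sweep(z, 2, apply(z, 2, max)))       # softmax, overflow-safe
    mu <- sweep(rel, 2, colSums(rel), "/") * rep(lib, each = p)
    k <- if (config$nb_dispersion > 0) {
      rnbinom(p * n, mu = as.vector(mu), size = 1 / config$nb_dispersion)
    } else {
      rpois(p * n, lambda = as.vector(mu))
    }
    matrix(k, nrow = p, ncol = n, dimnames = list(mirna_ids, ids))
  })

  truth <- list(prognostic_ids = mirna_ids[expr$prog],
                effect_sizes = config$effect_sizes,
                linear_predictor = as.numeric(lp),
                clinical_linear_predictor = as.numeric(lp_clin),
                mirna_linear_predictor = as.numeric(lp_mirna),
                prognostic_latent = u[expr$prog, , drop = FALSE],
                age_center = config$age_center)

  structure(list(counts = counts, clinical = clin, outcome = surv,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic miRNA-seq survival cohort\n")
  cat(sprintf("  %d patients, %d miRNAs (%d prognostic)\n",
              x$config$n_patients, x$config$n_mirnas, x$config$n_prognostic))
  cat(sprintf("  events: %d/%d (%.1f%%)\n", sum(x$outcome$dfs_event),
              nrow(x$outcome), 100 * mean(x$outcome$dfs_event)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `counts.tsv` (first column `mirna_id`, one column per sample),
#' `clinical.csv` (`patient_id,age,sex,stage,dfs_months,dfs_event`) and a
#' `truth.json` sidecar with the simulation ground truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_path <- file.path(dir, "counts.tsv")
  write_counts(cohort$counts, counts_path)
  clin <- merge(cohort$clinical, cohort$outcome, by = "patient_id", sort = FALSE)
  clin_path <- file.path(dir, "clinical.csv")
  write.csv(clin, clin_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth[c("prognostic_ids", "effect_sizes",
                                      "linear_predictor")],
                       truth_path, auto_unbox = FALSE, digits = NA)
  invisible(c(counts = counts_path, clinical = clin_path, truth = truth_path))
}
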