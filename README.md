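# mirsurv

Statistical workflow for developing and evaluating **prognostic
circulating-miRNA signatures** from small-RNA-seq counts with censored
survival outcomes — the setting of biomarker studies in resected
early-stage lung cancer, where a few hundred miRNAs survive count
filtering, cohorts hold ~200 patients, and only a quarter of them have
disease-free-survival (DFS) events.

The package implements, end to end:

* **Preprocessing** — third-quartile count filter (Q3 < 5 excluded),
  median/Q1 sample filter, TMM normalization, Blom rank-based
  inverse-normal transformation
  (Φ⁻¹((r − 3/8)/(n + 1/4))).
* **Modelling** — elastic-net penalized Cox regression
  (penalty λ[0.9‖β‖₁ + 0.05‖β‖₂²], λ by 5-fold cross-validated
  partial-likelihood deviance) for the miRNA-only (Model 1) and
  combined miRNA + clinical (Model 2) models; standard Cox with Wald
  intervals for the clinical-only Model 3 (sex, age, stage II vs I,
  stage IIIA vs I).
* **Cross-validated evaluation** — out-of-fold prognostic indices x'β
  (pre-validation with nested λ selection), median-split CV
  Kaplan–Meier curves, and the IPCW cumulative/dynamic time-dependent
  ROC and AUC at a 24-month landmark.
* **Permutation inference** — nulls for the CV log-rank statistic and
  for AUC = 0.5 (outcome rows shuffled against covariates, the whole CV
  re-run per permutation) and for the **added value** of the miRNAs
  over clinical factors (only the miRNA block permuted); add-one
  p-values, B = 500 by default.
* **Covariate screen** — per-miRNA Student t-tests against clinical
  covariates with Benjamini–Hochberg adjustment.
* **Synthetic cohorts** — a generator (Weibull–Cox survival over
  negative-binomial counts) producing cohorts with the structure the
  analysis assumes, including a stage-confounded negative-control mode.

## Worked example

```r
library(mirsurv)

cohort <- simulate_cohort(simulation_config(n_patients = 300, n_mirnas = 200,
                                            n_prognostic = 5, zero_fraction = 0,
                                            seed = 101))
clin <- merge(cohort$clinical, cohort$outcome, by = "patient_id", sort = FALSE)

report <- run_full_analysis(analysis_config(
  counts = list(cf = cohort$counts), clinical = clin,
  B = 100, seed = 101,
  control = penalized_control(nlambda = 30, lambda_min_ratio = 0.1, pmax = 60)))
report
```

```
Prognostic miRNA signature analysis report

== cf: n=300, events=116, median follow-up=36.0 months ==
  Model 1 (miRNA only): 10 miRNAs selected; CV AUC=0.792, CV log-rank=44.80
  Model 2 (combined):   22 predictors selected; CV AUC=0.716, CV log-rank=36.27
  Model 3 (clinical):   CV AUC=0.563, CV log-rank=3.91
  model1_mirna_only permutation p: log-rank 0.010, AUC 0.010
  model2_combined permutation p: log-rank 0.010, AUC 0.010
  model3_clinical_only permutation p: log-rank 0.030, AUC 0.020
  added value (Model 2 vs 3, shared-fold run): delta log-rank 48.06 (p=0.010), delta AUC 0.227 (p=0.010)
```

Reading the output: of the 5 planted prognostic miRNAs, Model 1's
coefficient table (`report$analyses$cf$model1$coefficients`) recovers
all 5 with correct signs among its 10 selections; out-of-fold
discrimination at the 24-month landmark is AUC ≈ 0.79 against 0.56 for
the clinical factors alone; and the added-value permutation test
(miRNA block permuted, B = 100) confirms the improvement at its
smallest attainable p-value, 1/101 ≈ 0.01. The added-value line is
computed on its own shared-fold draw, so its deltas need not equal the
difference of the per-model lines above it.

The methods vignette
(`vignettes/prognostic-mirna-workflow.Rmd`) documents the models, the
generator's assumptions, and every numerical convention.

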