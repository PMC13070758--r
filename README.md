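# gdmbalance

Clinical–microbiome risk modelling for gestational diabetes mellitus
(GDM) with compositional log-ratio balance features.

## What this package is for

Obstetric cohorts routinely screen GDM risk from clinical factors —
maternal age, pre-pregnancy BMI, previous GDM, fasting plasma glucose
(the "Clin4" set) — but gut-microbiome composition carries
complementary signal. `gdmbalance` implements the full analysis a
trial statistician needs to combine the two in a cohort of ~100 women
with ~20 outcome events:

* **Micro-balance feature.** From a genus-level abundance table
  (16S-style, rank-prefixed lineages), after normalisation, genus
  collapse (family proxies for unresolved genera) and a
  prevalence ≥ 15% / mean abundance ≥ 0.1% filter, a single log-ratio

  `balance = ln(b + ε) − ½[ln(d₁ + ε) + ln(d₂ + ε)]`,  ε = 10⁻⁶,

  with *Bifidobacterium* as numerator and *Phascolarctobacterium* and
  *Lachnoclostridium* as denominators (or data-driven nomination via a
  rank-sum screen).
* **Three logistic models** — clinical-only, microbiome-only,
  combined — fit by an in-package IRLS maximum-likelihood routine with
  Wald covariance.
* **Internal validation**: Mann–Whitney AUC with DeLong 95% intervals,
  Harrell-style bootstrap optimism correction (1000 draws by default),
  calibration slope/intercept by linear-predictor recalibration, and
  bias-corrected calibration curves with MAE / MSE / 90th-percentile
  error summaries.
* **Decision-curve analysis** over thresholds 0–0.60 with treat-all /
  treat-none references, standardized net benefit and case-control
  prevalence re-weighting.
* **A points-based nomogram** (0–100 scale) of the combined model.
* **Glycemic indices**: trapezoidal OGTT glucose AUC and incremental
  AUC over the 0/1/2-h grid, post-load excursions, IADPSG GDM
  classification (fasting ≥ 5.1, 1 h ≥ 10.0, 2 h ≥ 8.5 mmol/L),
  HOMA-IR, and IOM gestational-weight-gain categories.
* **Cohort statistics**: t / Mann–Whitney / Yates chi-square / Fisher
  comparisons and the pooled two-proportion sample-size formula.
* **A seeded synthetic cohort generator** (zero-inflated
  Dirichlet-multinomial compositions, logistic outcome on Clin4 +
  balance) so every stage is testable without participant-level data.

## Worked example

```r
library(gdmbalance)

# a trial-sized synthetic cohort: n = 98, ~22 GDM events
res <- run_pipeline(pipeline_config(seed = 1, n_bootstrap = 500))
res
#> <pipeline_result> n = 98, events = 22
#>   clin_only  AUC 0.719 (0.593-0.844)
#>   micro_only AUC 0.632 (0.493-0.770)
#>   combined   AUC 0.788 (0.681-0.896)
#>   combined corrected AUC 0.727 (B = 500)

res$validation
#> <validation_report> apparent AUC 0.788, optimism 0.061, corrected AUC 0.727
#>   calibration slope 0.721, intercept -0.276 (B = 500, skipped 20)
#>   curve MAE 0.0490, MSE 0.00285, p90 |err| 0.0699
```

The combined model's apparent AUC (0.788) beats the clinical-only
model (0.719); bootstrap resampling estimates that 0.061 of that is
optimism from fitting 5 predictors to 22 events, leaving a corrected
AUC of 0.727. A calibration slope below 1 (0.721) quantifies the same
overfit. The auto-nominated balance numerator on this cohort is
*Bifidobacterium*, recovering the planted protective direction.

Glycemic indices work on plain OGTT triplets (mmol/L at 0/1/2 h):

```r
ogtt_auc(ogtt_record(4.49, 8.88, 7.32))   # 14.785 mmol*h/L
ogtt_iauc(ogtt_record(4.49, 8.88, 7.32))  # 5.805
classify_gdm(ogtt_record(5.1, 6.0, 6.0))  # TRUE (fasting criterion)
chi2_yates(6, 44, 0, 48)$p_value          # 0.0398
```

A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`; cohorts round-trip through
`write_cohort()` / `read_cohort()` as plain CSV/TSV/JSON.

See the vignette (`vignettes/gdm-microbiome-risk.Rmd`) for the model,
its assumptions, and every numerical convention.

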