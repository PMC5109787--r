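# lassosim

Simulation benchmark of six L1-type variable selectors for binary logistic
regression on serum-biomarker-style panels.

## The problem

Biomarker discovery studies routinely fit a logistic model of a binary health
outcome on ~100 standardized candidate markers, of which only a handful carry
signal, with effects from very weak to strong, substantial inter-marker
correlation, and outcome prevalences around 40% or 12%. The question the
package answers by simulation: which L1-type selector best recovers the true
markers, and at what cost in false selections and out-of-sample
discrimination (AUC)?

## The model and methods

Every method minimizes the same penalized binomial deviance

```
-(1/N) Σ [ yᵢηᵢ − log(1 + exp(ηᵢ)) ]
  + λ₁ Σⱼ wⱼ [ ½(1−α)βⱼ² + α|βⱼ| ]  + λ₂ βᵀMβ
```

(intercept unpenalized), specialized by penalty configuration into six
selectors: **LASSO**, **adaptive LASSO** (MLE-pilot weights `1/|β̂ⱼ|`),
**elastic net** (joint CV over α = 0, 0.1, …, 1), **iterated LASSO**
(LASSO-pilot screening, then a second LASSO), **bootstrap-enhanced LASSO**
(100 resamples, keep variables selected in ≥75%), and **weighted fusion**
(correlation-driven quadratic fusion matrix `M`). Tuning is 10-fold
stratified cross-validation under deviance loss. The solver is
coordinate descent inside IRLS (C++/Rcpp) with strong-rule screening and a
full KKT rescan, so screening and warm starts never change the solution.
See `vignettes/methods.Rmd` for full definitions, solver numerics, and the
scenario design.

## Worked example

One replicate of scenario 3 (five true markers with coefficients
0.2, 0.4, 0.6, −0.6, 0.8 among 100 candidates, ρ = 0.2, 40% prevalence,
N = 1000), fit with the LASSO:

```r
library(lassosim)

spec <- scenario_spec(3, "overweight", n_train = 1000)
rep1 <- make_scenario_replicate(spec, replicate = 1, master_seed = 1)
fit  <- fit_method("lasso", rep1$train$X, rep1$train$y,
                   plan = tuning_plan(fold_seed = 42))
evaluate_replicate(fit, rep1$train, rep1$validation)
#>   method n_selected correct_nonzero correct_zero       auc
#> 1  lasso         10               5           90 0.7799215

fit$support
#> [1]  1  2  3  4  5 11 17 51 61 66
```

The LASSO recovers all five true markers (variables 1-5) plus five noise
variables — the familiar over-selection pattern that motivates the
comparison. Full study cells run through `study_config()` / `run_study()`:

```r
cfg <- study_config(scenarios = 3, outcomes = "overweight",
                    sample_sizes = 1000, methods = "lasso",
                    n_replicates = 100, master_seed = 1)
out <- run_study(cfg)
compare_report(out$summary)
```

## Analysis workflow

Numbered scripts under `analysis/` reproduce the study pipeline and write
tables under `results/`:

1. `analysis/01_calibrate_scenarios.R` — calibrate and verify the generator
   intercept for all 10 scenario × outcome cells (`results/calibration.csv`).
2. `analysis/02_run_simulation_study.R` — run a configurable slice of the
   scenario × method grid; per-replicate records are written incrementally
   and runs resume after interruption (`results/study/replicates.csv`).
3. `analysis/03_make_tables.R` — method-comparison tables, one per metric,
   cells formatted "median (min,max)" (`results/table_<metric>.csv`).

## Preprocessing real biomarker tables

`build_design_matrix()` converts a raw assay table (numeric strings plus a
below-detection sentinel such as `"<LOD"`) into a model-ready design matrix
using detectability rules: columns under 15% undetectable are
limit-substituted, imputed, log-transformed when skewed, and standardized;
15-49% are dichotomized at the median; 50-90% at detected/undetected; above
90% are dropped. The returned manifest records every decision.
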