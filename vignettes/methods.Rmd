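---
title: "Methods: penalized logistic selection and the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized logistic selection and the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lassosim` benchmarks six L1-type variable selectors for binary logistic
regression in the setting typical of serum-biomarker panels: around a hundred
standardized candidate predictors, a handful of genuinely associated markers
with effects ranging from weak to strong, substantial inter-marker
correlation, and outcome prevalences of roughly 40% or 12%. This vignette
documents the model, the solver numerics, the tuning protocol, and the
synthetic-data design, so that every number the package produces can be traced
to an explicit definition.

## 1. The penalized model

All six methods minimize the same objective, specialized by their penalty
configuration. For responses $y_i \in \{0,1\}$, standardized predictors
$x_i \in \mathbb{R}^p$, and linear predictor
$\eta_i = \beta_0 + x_i^\top \beta$:

$$
\ell(\beta_0, \beta) \;=\;
-\frac{1}{N}\sum_{i=1}^{N}\Big[y_i \eta_i - \log\!\big(1 + e^{\eta_i}\big)\Big]
\;+\; \lambda_1 \sum_{j=1}^{p} w_j\Big[\tfrac{1}{2}(1-\alpha)\beta_j^2
  + \alpha |\beta_j|\Big]
\;+\; \lambda_2\, \beta^\top M \beta .
$$

The intercept is never penalized. The pieces are:

* $w_j \ge 0$: per-coefficient L1 weights (all 1 for the plain LASSO;
  $w_j = \infty$ excludes coefficient $j$ exactly);
* $\alpha \in [0,1]$: elastic-net mixing between ridge and L1;
* $M$: a positive semi-definite fusion matrix encoding pairwise
  correlation structure, active only for weighted fusion.

With unit weights, $\alpha = 1$, $\lambda_2 = 0$ this is exactly the
`glmnet` binomial LASSO objective (same $1/N$ scaling), which the test suite
exploits as an independent oracle.

### The six selectors

| Method | Penalty configuration |
|---|---|
| LASSO | $w_j = 1$, $\alpha = 1$, $\lambda_2 = 0$ |
| Adaptive LASSO | $w_j = 1/\lvert\hat\beta_j\rvert^{v}$, $v = 1$, from a maximum-likelihood pilot fit; a ridge-penalized pilot substitutes when the MLE is unstable (non-convergence, fitted probabilities at 0/1, or exploding coefficients) |
| Elastic net | joint cross-validation over $\alpha \in \{0, 0.1, \dots, 1\}$ and the $\lambda$ path |
| Iterated LASSO | a LASSO pilot screens variables: coefficients at zero in the pilot get $w_j = \infty$ in a second LASSO |
| Bootstrap-enhanced LASSO (75%) | 100 bootstrap resamples, each LASSO-fit with its own cross-validated $\lambda$; keep variables selected in $\ge 75\%$ of resamples; report per-variable median coefficients over the resamples that selected them |
| Weighted fusion | $M$ built from $w_{ij} = \lvert\rho_{ij}\rvert^{\gamma} / (1 - \lvert\rho_{ij}\rvert)$ with $\gamma \in \{0.5, 1, 2.5, 5, 25\}$ and $\lambda_2 \in 10^{\,\mathrm{seq}(-4,\,2,\,\mathrm{len}=10)}$, jointly tuned with $\lambda_1$ |

## 2. Solver numerics

The core fitter (`fit_penalized_logistic()`) is an iteratively reweighted
least squares (IRLS) outer loop around cyclic coordinate descent, written in
C++ via Rcpp. Design choices that affect speed but are *exactness-preserving*
— every returned solution still satisfies the Karush-Kuhn-Tucker (KKT)
conditions of the stated objective to the requested tolerance:

* **Warm-started $\lambda$ paths.** Fits proceed from $\lambda_{\max}$ (the
  smallest $\lambda$ with an all-zero solution, scaled by $1 + 10^{-9}$ to
  guard against floating-point summation-order ties) down a log-spaced grid,
  each solution warm-starting the next.
* **Sequential strong rules with a full KKT rescan.** Coordinates unlikely to
  activate are screened out before cycling; after convergence the *full*
  gradient is checked and any violator re-enters, so screening can never
  change the solution. The final KKT gradient at one $\lambda$ is reused as
  the screening gradient for the next (the gradient is penalty-free, so this
  is exact, not approximate).
* **Covariance-form active-set updates.** When the active set stabilizes,
  the inner loop switches from residual updates to precomputed Gram-matrix
  updates (BLAS `dsyrk`), then reconciles residuals and runs a confirming
  full sweep plus the KKT rescan before accepting the solution.
* **Path early stop.** When training deviance falls below 0.1% of the null
  deviance the remaining (more overfit) path segment reuses the last
  solution.

`kkt_violation()` exposes the maximum KKT residual of any fit, and the test
suite certifies fits against a proximal-gradient (ISTA) oracle and, for the
fusion term, a brute-force objective evaluation on small problems.

## 3. Tuning protocol

All methods tune by 10-fold *stratified* cross-validation under the binomial
deviance loss, selecting the candidate with the smallest mean held-out
deviance. Ties break toward the strongest regularization: the largest
$\lambda_1$, then the largest $\alpha$ (candidates are ordered accordingly, so
the first minimum wins). The $\lambda$ grid has 50 points down to
$10^{-3}\lambda_{\max}$. Cross-validation fits use a coordinate tolerance of
$10^{-3}$ — verified on pilot grids to select identical candidates as
$10^{-7}$ — while the final refit at the chosen candidate uses $10^{-7}$.
Fold assignment derives from a dedicated seed so every method within a
replicate sees identical folds.

## 4. Synthetic data design

Predictor panels are equicorrelated Gaussians generated as
$x = \sqrt{\rho}\,u + \sqrt{1-\rho}\,z$ with a shared factor $u$, giving exact
compound symmetry with correlation $\rho$. Each scenario fixes $p = 100$
candidates of which $k$ carry signal:

| Scenario | $k$ | $\rho$ | 40%-outcome coefficients | 12%-outcome coefficients |
|---|---|---|---|---|
| 1 | 5 | 0.2 | 0.05, −0.05, 0.1, 0.15, 0.2 | 0.2, 0.4, 0.6, −0.6, 0.8 |
| 2 | 5 | 0.8 | same as 1 | same as 1 |
| 3 | 5 | 0.2 | 0.2, 0.4, 0.6, −0.6, 0.8 | 1, −1, 1.25, 1.5, 1.75 |
| 4 | 5 | 0.8 | same as 3 | same as 3 |
| 5 | 20 | 0.5 | $U(0.01, 0.2)$, redrawn per replicate | $U(0.1, 0.99)$, redrawn per replicate |

The intercept is *calibrated*, not asserted: under compound symmetry the
linear predictor $x^\top\beta$ is exactly
$N\!\big(0,\; (1-\rho)\sum_j \beta_j^2 + \rho\,(\sum_j \beta_j)^2\big)$, so
the marginal prevalence
$\mathbb{E}[\operatorname{logit}^{-1}(\beta_0 + x^\top\beta)]$ is a
one-dimensional integral, evaluated by adaptive quadrature
(`stats::integrate`) and solved for $\beta_0$ with `stats::uniroot`. This is
deterministic and accurate to quadrature precision — no Monte Carlo
calibration noise enters the generator. `analysis/01_calibrate_scenarios.R`
verifies the achieved prevalence by simulation (all cells within 0.1% of
target at 200,000 draws).

Each replicate draws an independent training set ($N = 1000$ or $500$) and an
equally sized validation set. Replicate streams derive from a master seed via
a 31-bit string-hash mixer, so any single (cell, replicate, method) fit can be
reproduced in isolation.

## 5. Evaluation

Per replicate and method we record: the number of selected variables, the
number of truly nonzero coefficients selected, the number of truly zero
coefficients correctly excluded, and the validation AUC, computed by the
midrank Mann-Whitney statistic (tie-aware, cross-checked against `pROC` and a
brute-force pair count in the tests). Cells are summarized by
median (min, max) over replicates, the convention used by the comparison
tables from `compare_report()`.

## 6. Applied-table preprocessing

For real biomarker tables, `build_design_matrix()` applies detectability
rules per column, based on the percentage of samples below the assay
detection limit: under 15% undetectable, substitute the limit, median-impute
other missingness, log-transform when skewness exceeds 1, and standardize;
15-49%, dichotomize at the column median; 50-90%, dichotomize at
detected/undetected; above 90%, drop the column. A manifest records the
decision and parameters for every column.

## 7. A small worked example

```{r example, eval = FALSE}
library(lassosim)

spec <- scenario_spec(3, "overweight", n_train = 1000)
rep1 <- make_scenario_replicate(spec, replicate = 1, master_seed = 1)

fit <- fit_method("lasso", rep1$train$X, rep1$train$y,
                  plan = tuning_plan(fold_seed = 42))
evaluate_replicate(fit, rep1$train, rep1$validation)
```

Larger runs go through `study_config()` / `run_study()`; see the scripts
under `analysis/` and the reproduction instructions in the README.

## 8. Limitations

* Scenario 5's per-replicate coefficient redraw means its "truth" varies
  across replicates by design; summaries there mix generator randomness with
  sampling noise.
* The bootstrap-enhanced LASSO re-tunes $\lambda$ inside each of 100
  resamples and is by far the most expensive method; budget accordingly.
* The solver targets $p$ in the hundreds with dense design matrices; it does
  not exploit sparsity in $X$.
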