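#' Scenario specification for the simulation study
#'
#' Encodes one cell of the five-scenario design: an equicorrelated panel of
#' `p` standardized Gaussian biomarkers, a sparse vector of true log-odds
#' coefficients on the standardized scale, and a target marginal outcome
#' prevalence (40% for the overweight outcome, 12% for the obese one).
#' Scenarios 1-4 carry five fixed non-zero coefficients; scenario 5 carries
#' twenty coefficients redrawn uniformly per dataset.
#'
#' @param scenario_id integer 1-5.
#' @param outcome_label `"overweight"` or `"obese"`.
#' @param n_train training-set size (1000 or 500 in the study design).
#' @param n_valid validation-set size; defaults to `n_train`.
#' @param p number of predictors.
#' @param rho common pairwise correlation; defaults to the scenario's design
#'   value (0.2, 0.8, 0.2, 0.8, 0.5).
#' @param target_prevalence marginal `P(y = 1)`; defaults to 0.40
#'   (overweight) or 0.12 (obese).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, outcome_label = c("overweight", "obese"),
                          n_train = 1000L, n_valid = n_train, p = 100L,
                          rho = NULL, target_prevalence = NULL) {
  outcome_label <- match.arg(outcome_label)
  if (!scenario_id %in% 1:5) stop("unsupported scenario_id: ", scenario_id)
  design <- scenario_design(scenario_id, outcome_label)
  if (is.null(rho)) rho <- design$rho
  if (is.null(target_prevalence))
    target_prevalence <- if (outcome_label == "overweight") 0.40 else 0.12
  stopifnot(rho >= 0, rho < 1, target_prevalence > 0, target_prevalence < 1,
            n_train >= 2, n_valid >= 2, p >= design$k)
  structure(list(scenario_id = as.integer(scenario_id),
                 outcome_label = outcome_label,
                 n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 p = as.integer(p), rho = rho,
                 coef_rule = design$coef_rule,
                 k = design$k,
                 target_prevalence = target_prevalence),
            class = "scenario_spec")
}

# Design table: number of signals, correlation, and non-zero coefficients
# (fixed vector, or uniform interval for scenario 5) per outcome.
scenario_design <- function(scenario_id, outcome_label) {
  weak <- c(0.05, -0.05, 0.1, 0.15, 0.2)
  moderate <- c(0.2, 0.4, 0.6, -0.6, 0.8)
  strong <- c(1, -1, 1.25, 1.5, 1.75)
  ow <- outcome_label == "overweight"
  switch(scenario_id,
    list(k = 5L, rho = 0.2,
         coef_rule = list(type = "fixed", values = if (ow) weak else moderate)),
    list(k = 5L, rho = 0.8,
         coef_rule = list(type = "fixed", values = if (ow) weak else moderate)),
    list(k = 5L, rho = 0.2,
         coef_rule = list(type = "fixed", values = if (ow) moderate else strong)),
    list(k = 5L, rho = 0.8,
         coef_rule = list(type = "fixed", values = if (ow) moderate else strong)),
    list(k = 20L, rho = 0.5,
         coef_rule = list(type = "uniform",
                          lo = if (ow) 0.01 else 0.1,
                          hi = if (ow) 0.2 else 0.99))
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario %d, %s: n=%d/%d, p=%d, rho=%.2f, prevalence=%.2f>\n",
              x$scenario_id, x$outcome_label, x$n_train, x$n_valid, x$p,
              x$rho, x$target_prevalence))
  invisible(x)
}

#' Generate equicorrelated standardized Gaussian predictors
#'
#' Draws an `n x p` matrix from a mean-zero multivariate normal with unit
#' variances and compound-symmetric correlation `rho` between every pair of
#' columns, using the exact one-factor representation
#' \eqn{x_{ij} = \sqrt{\rho}\, u_i + \sqrt{1-\rho}\, z_{ij}}.
#'
#' @param n,p dimensions.
#' @param rho common pairwise correlation in `[0, 1)`.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return numeric `n x p` matrix.
#' @export
generate_predictors <- function(n, p, rho, seed) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1) stop("invalid correlation: rho must be in [0, 1)")
  if (n < 1 || p < 1) stop("invalid dimension: n and p must be positive")
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0) return(Z)
  u <- stats::rnorm(n)
  sqrt(rho) * u + sqrt(1 - rho) * Z
}

#' Realize the true coefficient vector for a scenario
#'
#' Scenarios 1-4 place the fixed design vector in the first `k` positions of
#' a length-`p` vector padded with zeros; scenario 5 draws its `k = 20`
#' values independently and uniformly from the design interval (redrawn per
#' dataset), also in the leading positions.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed (used only by the uniform rule).
#' @return list with `beta` (length `p`) and `support`.
#' @export
realize_coefficients <- function(spec, seed = 1L) {
  beta <- rep(0, spec$p)
  rule <- spec$coef_rule
  if (rule$type == "fixed") {
    beta[seq_along(rule$values)] <- rule$values
  } else {
    set.seed(seed)
    beta[seq_len(spec$k)] <- stats::runif(spec$k, rule$lo, rule$hi)
  }
  list(beta = beta, support = which(beta != 0))
}

#' Calibrate the intercept to a target marginal prevalence
#'
#' Under compound symmetry the linear predictor contribution
#' \eqn{x^\top\beta} is exactly \eqn{N(0, \sigma^2)} with
#' \eqn{\sigma^2 = (1-\rho)\sum_j \beta_j^2 + \rho(\sum_j \beta_j)^2}, so the
#' marginal prevalence is the one-dimensional integral
#' \eqn{E[\mathrm{logit}^{-1}(\beta_0 + \sigma Z)]}, evaluated either by
#' adaptive quadrature (default; deterministic and exact to integration
#' tolerance) or by Monte Carlo on `mc_size` draws of \eqn{Z}, and solved for
#' \eqn{\beta_0} by root finding — the prevalence is monotone in
#' \eqn{\beta_0}.
#'
#' @param beta true coefficient vector.
#' @param rho common pairwise correlation of the predictors.
#' @param target_prevalence target `P(y = 1)` in `(0, 1)`.
#' @param method `"quadrature"` (default) or `"monte-carlo"`.
#' @param mc_size Monte-Carlo sample size (Monte-Carlo method only).
#' @param tol prevalence tolerance of the root.
#' @param seed integer seed (Monte-Carlo method only).
#' @return calibrated intercept `beta0`.
#' @export
calibrate_intercept <- function(beta, rho, target_prevalence,
                                method = c("quadrature", "monte-carlo"),
                                mc_size = 1e6, tol = 0.005, seed = 1L) {
  method <- match.arg(method)
  stopifnot(target_prevalence > 0, target_prevalence < 1, tol > 0)
  sigma2 <- (1 - rho) * sum(beta^2) + rho * sum(beta)^2
  if (sigma2 == 0) return(stats::qlogis(target_prevalence))
  sigma <- sqrt(sigma2)
  if (method == "quadrature") {
    f <- function(b0) {
      stats::integrate(function(z) stats::plogis(b0 + sigma * z) *
                         stats::dnorm(z), -Inf, Inf,
                       rel.tol = 1e-10)$value - target_prevalence
    }
  } else {
    set.seed(seed)
    v <- stats::rnorm(mc_size, sd = sigma)
    f <- function(b0) mean(stats::plogis(b0 + v)) - target_prevalence
  }
  if (f(-50) > 0 || f(50) < 0)
    stop("calibration failure: root not bracketed within |beta0| <= 50")
  r <- stats::uniroot(f, c(-50, 50), tol = min(tol / 10, 1e-6))
  if (abs(f(r$root)) > tol)
    stop("calibration failure: prevalence outside tolerance at the root")
  r$root
}

#' Draw binary outcomes from a logistic model
#'
#' \eqn{y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 +
#' x_i^\top\beta))}, independently; the linear predictor is clipped to
#' \eqn{\pm 35} before the inverse link to guard against overflow.
#'
#' @param X predictor matrix.
#' @param model list with `beta0` and `beta` (a true model).
#' @param seed integer seed.
#' @return integer vector of 0/1 outcomes.
#' @export
generate_outcome <- function(X, model, seed) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$beta)) stop("dimension mismatch")
  eta <- pmin(pmax(drop(model$beta0 + X %*% model$beta), -35), 35)
  set.seed(seed)
  stats::rbinom(nrow(X), 1L, stats::plogis(eta))
}

# Cache of calibrated intercepts for fixed-coefficient scenarios, keyed by
# the generative parameters (the calibration is deterministic given them).
.calib_cache <- new.env(parent = emptyenv())

calibrated_true_model <- function(spec, replicate_index, master_seed) {
  if (spec$coef_rule$type == "fixed") {
    cf <- realize_coefficients(spec)
    key <- paste(spec$scenario_id, spec$outcome_label, spec$p, spec$rho,
                 spec$target_prevalence, master_seed, sep = "|")
    if (!is.null(.calib_cache[[key]])) {
      beta0 <- .calib_cache[[key]]
    } else {
      beta0 <- calibrate_intercept(cf$beta, spec$rho, spec$target_prevalence,
                                   seed = mix_seed(master_seed, "calib",
                                                   spec$scenario_id,
                                                   spec$outcome_label))
      .calib_cache[[key]] <- beta0
    }
  } else {
    cf <- realize_coefficients(spec, seed = mix_seed(master_seed, "coef",
                                                     spec$scenario_id,
                                                     spec$outcome_label,
                                                     spec$n_train,
                                                     replicate_index))
    beta0 <- calibrate_intercept(cf$beta, spec$rho, spec$target_prevalence,
                                 seed = mix_seed(master_seed, "calib",
                                                 spec$scenario_id,
                                                 spec$outcome_label,
                                                 spec$n_train,
                                                 replicate_index))
  }
  list(beta0 = beta0, beta = cf$beta, support = cf$support)
}

#' Generate one train/validation replicate of a scenario
#'
#' Both datasets share the same true model (calibrated intercept and,
#' for scenario 5, the per-replicate coefficient draw) but use disjoint
#' random streams derived deterministically from `(master_seed,
#' replicate_index)`, so any replicate is reproducible in isolation.
#'
#' @param spec a [scenario_spec()].
#' @param replicate_index replicate number (any integer tag).
#' @param master_seed master integer seed.
#' @return list with `train` and `validation` datasets; each is a list with
#'   `X`, `y`, `truth`, `seed`, and `role`.
#' @export
make_scenario_replicate <- function(spec, replicate_index, master_seed) {
  truth <- calibrated_true_model(spec, replicate_index, master_seed)
  mk <- function(n, role) {
    sx <- mix_seed(master_seed, role, "X", spec$scenario_id,
                   spec$outcome_label, spec$n_train, replicate_index)
    sy <- mix_seed(master_seed, role, "y", spec$scenario_id,
                   spec$outcome_label, spec$n_train, replicate_index)
    X <- generate_predictors(n, spec$p, spec$rho, sx)
    colnames(X) <- paste0("x", seq_len(spec$p))
    list(X = X, y = generate_outcome(X, truth, sy), truth = truth,
         seed = sx, role = role)
  }
  list(train = mk(spec$n_train, "train"),
       validation = mk(spec$n_valid, "validation"))
}

#' Write a simulated dataset to CSV with a JSON sidecar
#'
#' The CSV holds columns `x1..xp` and `y`; the sidecar records the true
#' model and the seed so the dataset is self-describing.
#'
#' @param dataset a dataset as produced by [make_scenario_replicate()].
#' @param path CSV file path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$X)
  df$y <- dataset$y
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sprintf(
    '{"role": "%s", "seed": %d, "beta0": %.10g, "beta": [%s], "support": [%s]}',
    dataset$role, dataset$seed, dataset$truth$beta0,
    paste(sprintf("%.10g", dataset$truth$beta), collapse = ", "),
    paste(dataset$truth$support, collapse = ", "))
  writeLines(sidecar, paste0(path, ".json"))
  invisible(path)
}
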