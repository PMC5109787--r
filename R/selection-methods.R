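#' Cross-validation tuning plan
#'
#' Shared tuning protocol for all six selectors: 10-fold cross validation
#' with binomial deviance loss, an elastic-net mixing grid from 0 to 1 in
#' steps of 0.1, fusion exponents `gamma` in (0.5, 1, 2.5, 5, 25), and a
#' log-spaced `lambda2` grid. The adaptive-weight exponent `v` defaults to 1.
#'
#' @param n_folds number of CV folds.
#' @param n_lambda,lambda_ratio L1 path resolution, see [lambda_path()].
#' @param alpha_grid elastic-net mixing candidates.
#' @param gamma_grid weighted-fusion exponent candidates.
#' @param lambda2_grid fusion-scale candidates.
#' @param v_exponent exponent of the adaptive/iterated weights
#'   \eqn{w_j = 1/|\hat\beta_j|^v}.
#' @param fold_seed integer seed of the stratified fold assignment (and of
#'   bootstrap resampling in the bootstrap-enhanced LASSO).
#' @param cv_tol solver tolerance of the fold fits during tuning; only the
#'   held-out deviance is read off these fits, so it can be looser than the
#'   final-fit tolerance of `1e-7`.
#' @return an object of class `tuning_plan`.
#' @export
tuning_plan <- function(n_folds = 10L, n_lambda = 50L, lambda_ratio = 1e-3,
                        alpha_grid = seq(0, 1, by = 0.1),
                        gamma_grid = c(0.5, 1, 2.5, 5, 25),
                        lambda2_grid = 10^seq(-4, 2, length.out = 10),
                        v_exponent = 1, fold_seed = 1L, cv_tol = 1e-3) {
  stopifnot(n_folds >= 2, n_lambda >= 1, length(alpha_grid) >= 1,
            length(gamma_grid) >= 1, length(lambda2_grid) >= 1,
            v_exponent > 0, cv_tol > 0)
  structure(list(n_folds = as.integer(n_folds),
                 n_lambda = as.integer(n_lambda),
                 lambda_ratio = lambda_ratio,
                 alpha_grid = alpha_grid, gamma_grid = gamma_grid,
                 lambda2_grid = lambda2_grid, v_exponent = v_exponent,
                 fold_seed = as.integer(fold_seed), cv_tol = cv_tol),
            class = "tuning_plan")
}

#' Stratified cross-validation folds
#'
#' Assigns fold labels separately within each outcome class so every fold
#' contains both classes; required for the 12%-prevalence outcome.
#'
#' @param y 0/1 outcome vector.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold labels of length `length(y)`.
#' @export
make_cv_folds <- function(y, n_folds, seed) {
  if (min(table(y)) < n_folds)
    stop("each class must have at least n_folds members for stratified folds")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

held_out_deviance <- function(eta, y) {
  pr <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  -2 * (y * log(pr) + (1 - y) * log(1 - pr))
}

# A tuning candidate: alpha, per-coefficient L1 weights, lambda2, fusion
# exponent gamma (matrix rebuilt inside each training fold), and its own
# decreasing lambda sequence.
make_candidate <- function(alpha, lambdas, l1_weights = 1, lambda2 = 0,
                           gamma = NA_real_) {
  list(alpha = alpha, lambdas = lambdas, l1_weights = l1_weights,
       lambda2 = lambda2, gamma = gamma)
}

# Cross-validated grid search over candidates x their lambda sequences.
# Candidates must be ordered so that earlier entries are preferred on ties
# (within a candidate, larger lambdas come first). Returns the winning
# candidate, its lambda, and the CV deviance table.
cv_select <- function(X, y, folds, candidates, tol = 1e-3) {
  n <- nrow(X); p <- ncol(X)
  best <- NULL
  cv_table <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    w <- cand$l1_weights
    if (length(w) == 1L) w <- rep(w, p)
    dev_sum <- numeric(length(cand$lambdas))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      M <- if (cand$lambda2 > 0)
        make_fusion_matrix(Xtr, cand$gamma)$fusion_matrix else NULL
      path <- cpp_cd_path(Xtr, as.double(y[tr]), cand$alpha,
                          cand$lambdas, as.double(w), cand$lambda2, M,
                          100L, 10000L, tol)
      eta <- cbind(1, X[!tr, , drop = FALSE]) %*% path$coefs
      dev_sum <- dev_sum + colSums(held_out_deviance(eta, y[!tr]))
    }
    dev_mean <- dev_sum / n
    cv_table[[ci]] <- data.frame(candidate = ci, alpha = cand$alpha,
                                 lambda2 = cand$lambda2, gamma = cand$gamma,
                                 lambda = cand$lambdas, cv_deviance = dev_mean)
    li <- which.min(dev_mean) # first (largest-lambda) minimum
    if (is.null(best) || dev_mean[li] < best$deviance) {
      best <- list(candidate = cand, lambda = cand$lambdas[li],
                   deviance = dev_mean[li])
    }
  }
  best$cv_table <- do.call(rbind, cv_table)
  best
}

# Refit on the full data at the winning tuning point, warm-starting down the
# candidate's lambda sequence for stability.
refit_at <- function(X, y, cand, lambda, method) {
  p <- ncol(X)
  w <- cand$l1_weights
  if (length(w) == 1L) w <- rep(w, p)
  M <- if (cand$lambda2 > 0)
    make_fusion_matrix(X, cand$gamma)$fusion_matrix else NULL
  lams <- cand$lambdas[cand$lambdas >= lambda - 1e-12]
  if (!length(lams) || abs(lams[length(lams)] - lambda) > 1e-12)
    lams <- c(lams, lambda)
  path <- cpp_cd_path(X, as.double(y), cand$alpha, lams, as.double(w),
                      cand$lambda2, M, 100L, 10000L, 1e-7)
  k <- length(lams)
  beta0 <- path$coefs[1, k]
  beta <- path$coefs[-1, k]
  pen <- penalty_spec(lambda1 = lambda, alpha = cand$alpha, l1_weights = w,
                      lambda2 = cand$lambda2, fusion_matrix = M)
  new_fit_result(method, beta0, beta, pen,
                 objective = penalized_objective(X, y, beta0, beta, pen),
                 converged = path$converged[k], iterations = NA_integer_,
                 tuning = list(gamma = cand$gamma))
}

#' Cross-validated tuning for a named selector
#'
#' Runs the 10-fold deviance-loss grid search that each selector uses
#' internally and returns the chosen tuning values. Ties are broken toward
#' the sparsest-inducing point (largest lambda, then largest alpha).
#'
#' @param X,y data.
#' @param method one of `"lasso"`, `"elastic_net"`, `"weighted_fusion"`.
#'   (The adaptive, iterated, and bootstrap selectors tune through their own
#'   staged protocols; see [fit_adaptive_lasso()] and friends.)
#' @param plan a [tuning_plan()].
#' @return list with the chosen `lambda`, `alpha`, `lambda2`, `gamma`, the
#'   achieved CV `deviance`, and the full `cv_table`.
#' @export
cv_tune <- function(X, y, method = c("lasso", "elastic_net", "weighted_fusion"),
                    plan = tuning_plan()) {
  method <- match.arg(method)
  folds <- make_cv_folds(y, plan$n_folds, plan$fold_seed)
  cands <- build_candidates(X, y, method, plan)
  best <- cv_select(X, y, folds, cands, plan$cv_tol)
  list(lambda = best$lambda, alpha = best$candidate$alpha,
       lambda2 = best$candidate$lambda2, gamma = best$candidate$gamma,
       deviance = best$deviance, cv_table = best$cv_table)
}

build_candidates <- function(X, y, method, plan) {
  if (method == "lasso") {
    list(make_candidate(1, lambda_path(X, y, 1, plan$n_lambda,
                                       plan$lambda_ratio)))
  } else if (method == "elastic_net") {
    # alpha descending so ties prefer the sparser (more-L1) candidate
    lapply(sort(plan$alpha_grid, decreasing = TRUE), function(a)
      make_candidate(a, lambda_path(X, y, a, plan$n_lambda,
                                    plan$lambda_ratio)))
  } else if (method == "weighted_fusion") {
    # lambda2 ascending after gamma so ties prefer the least-fused candidate
    lams <- lambda_path(X, y, 1, plan$n_lambda, plan$lambda_ratio)
    cands <- list()
    for (g in plan$gamma_grid)
      for (l2 in sort(plan$lambda2_grid))
        cands[[length(cands) + 1L]] <-
          make_candidate(1, lams, lambda2 = l2, gamma = g)
    cands
  } else stop("unknown method: ", method)
}

intercept_only_fit <- function(X, y, method) {
  b0 <- min(max(stats::qlogis(mean(y)), -35), 35)
  pen <- penalty_spec()
  new_fit_result(method, b0, rep(0, ncol(X)), pen,
                 objective = penalized_objective(X, y, b0, rep(0, ncol(X)), pen),
                 converged = TRUE, iterations = 0L)
}

#' LASSO with cross-validated lambda
#'
#' Pure L1 penalty (`alpha = 1`, unit weights, no fusion), lambda chosen by
#' 10-fold CV under deviance loss.
#'
#' @param X,y data.
#' @param plan a [tuning_plan()].
#' @return a `fit_result`.
#' @export
fit_lasso <- function(X, y, plan = tuning_plan()) {
  folds <- make_cv_folds(y, plan$n_folds, plan$fold_seed)
  best <- cv_select(X, y, folds, build_candidates(X, y, "lasso", plan),
                    plan$cv_tol)
  refit_at(X, y, best$candidate, best$lambda, "lasso")
}

#' Elastic net with jointly cross-validated alpha and lambda
#'
#' CV over the full `alpha_grid x lambda_path(alpha)` product; each alpha
#' gets its own lambda sequence.
#'
#' @inheritParams fit_lasso
#' @return a `fit_result`.
#' @export
fit_elastic_net <- function(X, y, plan = tuning_plan()) {
  folds <- make_cv_folds(y, plan$n_folds, plan$fold_seed)
  best <- cv_select(X, y, folds, build_candidates(X, y, "elastic_net", plan),
                    plan$cv_tol)
  refit_at(X, y, best$candidate, best$lambda, "elastic_net")
}

#' Per-coefficient adaptive weights from a pilot estimate
#'
#' \eqn{w_j = 1/|\hat\beta_j|^v}; a pilot coefficient of exactly zero yields
#' an infinite weight, which excludes the variable.
#'
#' @param beta_hat pilot coefficient vector.
#' @param v positive exponent.
#' @return weight vector.
#' @export
adaptive_weights <- function(beta_hat, v = 1) {
  stopifnot(v > 0)
  ifelse(beta_hat == 0, Inf, 1 / abs(beta_hat)^v)
}

#' Adaptive LASSO (maximum-likelihood pilot weights)
#'
#' Stage 1 fits the unpenalized logistic MLE (ridge-stabilized on
#' separation); stage 2 fits a weighted LASSO with
#' \eqn{w_j = 1/|\hat\beta_j|^v} and CV-tuned lambda.
#'
#' @inheritParams fit_lasso
#' @return a `fit_result`; `tuning$stabilized` records whether the pilot
#'   needed the ridge fallback.
#' @export
fit_adaptive_lasso <- function(X, y, plan = tuning_plan()) {
  pilot <- mle_logistic(X, y)
  w <- adaptive_weights(pilot$beta, plan$v_exponent)
  fit <- fit_weighted_l1(X, y, w, plan, "adaptive_lasso")
  fit$tuning$stabilized <- pilot$stabilized
  fit
}

# Weighted-L1 CV fit shared by the adaptive and iterated LASSO stages.
fit_weighted_l1 <- function(X, y, w, plan, method) {
  if (all(is.infinite(w))) return(intercept_only_fit(X, y, method))
  folds <- make_cv_folds(y, plan$n_folds, plan$fold_seed)
  cand <- make_candidate(1, lambda_path(X, y, 1, plan$n_lambda,
                                        plan$lambda_ratio, l1_weights = w),
                         l1_weights = w)
  best <- cv_select(X, y, folds, list(cand), plan$cv_tol)
  refit_at(X, y, best$candidate, best$lambda, method)
}

#' Iterated LASSO (LASSO pilot weights and screening)
#'
#' Stage 1 is a CV-tuned LASSO; variables it zeroes are excluded outright,
#' and the survivors are refit with a weighted LASSO using weights
#' \eqn{1/|\hat\beta_{lasso,j}|^v}. The result's support is always a subset
#' of the stage-1 support.
#'
#' @inheritParams fit_lasso
#' @return a `fit_result`.
#' @export
fit_iterated_lasso <- function(X, y, plan = tuning_plan()) {
  stage1 <- fit_lasso(X, y, plan)
  if (!length(stage1$support)) return(intercept_only_fit(X, y, "iterated_lasso"))
  w <- adaptive_weights(stage1$beta, plan$v_exponent)
  fit_weighted_l1(X, y, w, plan, "iterated_lasso")
}

#' Bootstrap selection aggregate
#'
#' Per-variable non-zero frequency across bootstrap fits, the set selected
#' at the frequency threshold, and median coefficients (medians reported
#' only for selected variables, zero elsewhere).
#'
#' @param beta0s vector of bootstrap intercepts.
#' @param beta_mat `n_boot x p` matrix of bootstrap coefficients.
#' @param threshold selection-frequency threshold (default 0.75).
#' @return list with `n_boot`, `selection_frequency`, `threshold`,
#'   `selected`, `median_beta0`, `median_beta`.
#' @export
bootstrap_aggregate <- function(beta0s, beta_mat, threshold = 0.75) {
  freq <- colMeans(beta_mat != 0)
  selected <- which(freq >= threshold)
  med <- apply(beta_mat, 2, stats::median)
  med[-selected] <- 0
  if (!length(selected)) med[] <- 0
  list(n_boot = nrow(beta_mat), selection_frequency = freq,
       threshold = threshold, selected = selected,
       median_beta0 = stats::median(beta0s), median_beta = med)
}

#' Bootstrap-enhanced LASSO with a 75% stability rule
#'
#' Fits a CV-tuned LASSO on `n_boot` bootstrap resamples (with replacement,
#' size `n`; lambda re-tuned within each resample), keeps the variables that
#' appear in at least `threshold` of the resamples, and reports per-variable
#' median coefficients over the bootstrap fits for the kept variables (zero
#' elsewhere) with the median intercept.
#'
#' @inheritParams fit_lasso
#' @param n_boot number of bootstrap resamples.
#' @param threshold selection-frequency threshold.
#' @return list with `fit` (a `fit_result` built from the median
#'   coefficients) and `aggregate` (see [bootstrap_aggregate()]).
#' @export
fit_bl75 <- function(X, y, plan = tuning_plan(), n_boot = 100L,
                     threshold = 0.75) {
  stopifnot(n_boot >= 2)
  n <- nrow(X); p <- ncol(X)
  beta_mat <- matrix(0, n_boot, p)
  beta0s <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- NULL
    for (attempt in 1:10) {
      set.seed(mix_seed(plan$fold_seed, "boot", b, attempt))
      cand_idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[cand_idx])) == 2L &&
          min(table(y[cand_idx])) >= plan$n_folds) { idx <- cand_idx; break }
    }
    if (is.null(idx)) stop("bootstrap resample degenerate after 10 attempts")
    bplan <- plan
    bplan$fold_seed <- mix_seed(plan$fold_seed, "bootfold", b)
    fit <- fit_lasso(X[idx, , drop = FALSE], y[idx], bplan)
    beta_mat[b, ] <- fit$beta
    beta0s[b] <- fit$beta0
  }
  agg <- bootstrap_aggregate(beta0s, beta_mat, threshold)
  pen <- penalty_spec()
  fit <- new_fit_result("bl75", agg$median_beta0, agg$median_beta, pen,
                        objective = penalized_objective(X, y, agg$median_beta0,
                                                        agg$median_beta, pen),
                        converged = TRUE, iterations = n_boot,
                        tuning = list(n_boot = n_boot, threshold = threshold))
  list(fit = fit, aggregate = agg)
}

#' Weighted fusion with cross-validated gamma, lambda2, and lambda1
#'
#' L1 penalty plus the correlation-driven quadratic of
#' [make_fusion_matrix()]; CV jointly over the gamma grid, the lambda2 grid,
#' and the lambda1 path (fusion weights rebuilt within each training fold).
#'
#' @inheritParams fit_lasso
#' @return a `fit_result`; `tuning$gamma` and `tuning$lambda2` record the
#'   chosen fusion parameters.
#' @export
fit_weighted_fusion <- function(X, y, plan = tuning_plan()) {
  stopifnot(ncol(X) >= 2)
  folds <- make_cv_folds(y, plan$n_folds, plan$fold_seed)
  best <- cv_select(X, y, folds,
                    build_candidates(X, y, "weighted_fusion", plan),
                    plan$cv_tol)
  refit_at(X, y, best$candidate, best$lambda, "weighted_fusion")
}

#' Method registry
#'
#' Uniform entry point for the six selectors.
#'
#' @param method one of `"lasso"`, `"adaptive_lasso"`, `"elastic_net"`,
#'   `"iterated_lasso"`, `"bl75"`, `"weighted_fusion"`.
#' @param X,y data.
#' @param plan a [tuning_plan()].
#' @param n_boot bootstrap count for `"bl75"`.
#' @return a `fit_result` (for `"bl75"`, the median-coefficient fit; the
#'   full aggregate is available through [fit_bl75()]).
#' @export
fit_method <- function(method, X, y, plan = tuning_plan(), n_boot = 100L) {
  switch(method,
         lasso = fit_lasso(X, y, plan),
         adaptive_lasso = fit_adaptive_lasso(X, y, plan),
         elastic_net = fit_elastic_net(X, y, plan),
         iterated_lasso = fit_iterated_lasso(X, y, plan),
         bl75 = fit_bl75(X, y, plan, n_boot)$fit,
         weighted_fusion = fit_weighted_fusion(X, y, plan),
         stop("unknown method: ", method))
}

#' @rdname fit_method
#' @export
selection_methods <- function() {
  c("lasso", "adaptive_lasso", "elastic_net", "iterated_lasso", "bl75",
    "weighted_fusion")
}
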