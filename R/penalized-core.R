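#' Penalty specification for the unified L1/elastic-net/fusion family
#'
#' Describes the penalty
#' \deqn{\lambda_1 \sum_j w_j\left[\tfrac{1}{2}(1-\alpha)\beta_j^2 +
#'   \alpha|\beta_j|\right] + \lambda_2\,\beta^\top M \beta,}
#' which covers the LASSO (\eqn{\alpha=1}, unit weights, \eqn{\lambda_2=0}),
#' ridge (\eqn{\alpha=0}), the elastic net, per-coefficient weighted L1
#' (adaptive and iterated LASSO), and weighted fusion (\eqn{\lambda_2>0} with
#' a correlation-driven matrix \eqn{M}). The intercept is never penalized.
#'
#' @param lambda1 non-negative L1/elastic-net scale.
#' @param alpha elastic-net mixing proportion in `[0, 1]`; 1 is pure L1.
#' @param l1_weights vector of non-negative per-coefficient multipliers;
#'   `Inf` forces the coefficient to exactly zero. Recycled to length `p`
#'   when scalar.
#' @param lambda2 non-negative scale of the quadratic fusion term.
#' @param fusion_matrix symmetric positive-semidefinite `p x p` matrix `M`
#'   with \eqn{J(\beta) = \beta^\top M \beta}, or `NULL` when `lambda2 = 0`.
#' @return an object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda1 = 0, alpha = 1, l1_weights = 1,
                         lambda2 = 0, fusion_matrix = NULL) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, alpha >= 0, alpha <= 1,
            all(l1_weights >= 0))
  if (lambda2 > 0 && is.null(fusion_matrix))
    stop("lambda2 > 0 requires a fusion_matrix")
  if (!is.null(fusion_matrix)) {
    if (!isSymmetric(unname(fusion_matrix), tol = 1e-8))
      stop("fusion_matrix must be symmetric")
  }
  structure(list(lambda1 = lambda1, alpha = alpha, l1_weights = l1_weights,
                 lambda2 = lambda2, fusion_matrix = fusion_matrix),
            class = "penalty_spec")
}

expand_weights <- function(penalty, p) {
  w <- penalty$l1_weights
  if (length(w) == 1L) w <- rep(w, p)
  if (length(w) != p) stop("l1_weights length must be 1 or p")
  w
}

#' Numerically stable log(1 + exp(eta))
#' @noRd
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

#' Penalized negative log-likelihood objective
#'
#' The average binomial negative log-likelihood
#' \eqn{-(1/N)\sum_i [y_i\eta_i - \log(1+e^{\eta_i})]} plus the penalty of
#' [penalty_spec()]. Penalties are not averaged by `N`. An infinite L1
#' weight paired with a non-zero coefficient yields `+Inf`.
#'
#' @param X numeric `n x p` predictor matrix.
#' @param y binary outcome vector in `{0, 1}`.
#' @param beta0 intercept.
#' @param beta coefficient vector of length `p`.
#' @param penalty a [penalty_spec()].
#' @return scalar objective value.
#' @export
penalized_objective <- function(X, y, beta0, beta, penalty) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) stop("beta length does not match ncol(X)")
  if (nrow(X) != length(y)) stop("y length does not match nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  w <- expand_weights(penalty, ncol(X))
  if (any(is.infinite(w) & beta != 0)) return(Inf)
  eta <- drop(beta0 + X %*% beta)
  nll <- -mean(y * eta - log1pexp(eta))
  wf <- ifelse(is.infinite(w), 0, w) # coefficients there are exactly 0
  pen1 <- penalty$lambda1 *
    sum(wf * (0.5 * (1 - penalty$alpha) * beta^2 + penalty$alpha * abs(beta)))
  pen2 <- if (penalty$lambda2 > 0)
    penalty$lambda2 * drop(crossprod(beta, penalty$fusion_matrix %*% beta))
  else 0
  nll + pen1 + pen2
}

#' Fit penalized binomial logistic regression
#'
#' Solves the penalized objective of [penalized_objective()] by iteratively
#' reweighted least squares with cyclic coordinate descent, soft-thresholding
#' the L1 part and treating the fusion quadratic exactly (full off-diagonal
#' coupling, no diagonal approximation). Deterministic given its inputs.
#'
#' @param X,y predictors and 0/1 outcomes.
#' @param penalty a [penalty_spec()].
#' @param init optional list with `beta0` and `beta` warm-start values.
#' @param max_iter maximum outer (IRLS) iterations.
#' @param tol convergence threshold on the maximum absolute coefficient
#'   change between outer iterations.
#' @param method label stored on the result.
#' @return a `fit_result`: list with `method`, `beta0`, `beta`, `support`
#'   (indices of exactly non-zero coefficients), `penalty` (the realized
#'   [penalty_spec()]), `tuning`, `objective`, `converged`, and `iterations`.
#' @export
fit_penalized_logistic <- function(X, y, penalty, init = NULL,
                                   max_iter = 100L, tol = 1e-7,
                                   method = "penalized_logistic") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length does not match nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  w <- expand_weights(penalty, p)
  if (length(unique(y)) < 2L) {
    warning("outcome has a single class; returning intercept-only fit")
    b0 <- stats::qlogis(min(max(mean(y), 1e-12), 1 - 1e-12))
    b0 <- min(max(b0, -35), 35)
    return(new_fit_result(method, b0, rep(0, p), penalty,
                          objective = penalized_objective(X, y, b0, rep(0, p), penalty),
                          converged = TRUE, iterations = 0L))
  }
  b0 <- if (!is.null(init$beta0)) init$beta0 else 0
  b <- if (!is.null(init$beta)) init$beta else rep(0, p)
  fit <- cpp_cd_fit(X, as.double(y), penalty$alpha, penalty$lambda1,
                    as.double(w), penalty$lambda2,
                    penalty$fusion_matrix, b0, as.double(b),
                    as.integer(max_iter), 10000L, tol)
  beta <- as.double(fit$beta)
  new_fit_result(method, fit$beta0, beta, penalty,
                 objective = penalized_objective(X, y, fit$beta0, beta, penalty),
                 converged = fit$converged, iterations = fit$iterations)
}

new_fit_result <- function(method, beta0, beta, penalty, objective,
                           converged, iterations, tuning = list()) {
  structure(list(method = method, beta0 = beta0, beta = beta,
                 support = which(beta != 0),
                 penalty = penalty,
                 tuning = c(list(lambda1 = penalty$lambda1,
                                 alpha = penalty$alpha,
                                 lambda2 = penalty$lambda2), tuning),
                 objective = objective, converged = converged,
                 iterations = iterations),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>\n", x$method))
  cat(sprintf("  non-zero coefficients: %d of %d\n",
              length(x$support), length(x$beta)))
  cat(sprintf("  intercept: %.4f  objective: %.6f  converged: %s\n",
              x$beta0, x$objective, x$converged))
  invisible(x)
}

#' Correlation-driven fusion weights and quadratic-form matrix
#'
#' For standardized predictor columns with pairwise sample correlations
#' \eqn{\rho_{ij}}, the fusion weights are
#' \eqn{w_{ij} = |\rho_{ij}|^\gamma / (1 - |\rho_{ij}|)} with sign
#' \eqn{s_{ij} = \mathrm{sign}(\rho_{ij})}, and the quadratic penalty is
#' \eqn{J(\beta) = (1/p) \sum_{i<j} w_{ij} (\beta_i - s_{ij}\beta_j)^2}.
#' The returned matrix `M` satisfies \eqn{\beta^\top M \beta = J(\beta)},
#' with \eqn{M_{ii} = (1/p)\sum_{j\ne i} w_{ij}} and
#' \eqn{M_{ij} = -(1/p) w_{ij} s_{ij}}. Absolute correlations are capped at
#' \eqn{1 - 10^{-6}} so the weights stay finite.
#'
#' @param X predictor matrix with at least two columns.
#' @param gamma positive tuning exponent.
#' @return list with `gamma`, `rho_matrix`, `sign_matrix`, `weight_matrix`,
#'   and the quadratic-form matrix `fusion_matrix`.
#' @export
make_fusion_matrix <- function(X, gamma) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(gamma > 0, p >= 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s); treating their correlations as zero")
  }
  rho <- suppressWarnings(stats::cor(X))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  a <- pmin(abs(rho), 1 - 1e-6)
  w <- a^gamma / (1 - a)
  s <- sign(rho)
  diag(w) <- 0
  M <- -(w * s) / p
  diag(M) <- rowSums(w) / p
  list(gamma = gamma, rho_matrix = rho, sign_matrix = s,
       weight_matrix = w, fusion_matrix = M)
}

#' Lambda sequence for the L1 path
#'
#' Largest value \eqn{\lambda_{max} = \max_j |x_j^\top (y - \bar y)| /
#' (N \max(\alpha, 0.001) w_j)} (the smallest lambda at which all penalized
#' coefficients are zero when \eqn{\alpha = 1}), followed by `n_lambda`
#' log-spaced values down to `lambda_max * ratio`.
#'
#' @param X,y data; `y` must contain both classes.
#' @param alpha elastic-net mixing value used for the `alpha` floor.
#' @param n_lambda number of grid points.
#' @param ratio ratio of the smallest to the largest lambda.
#' @param l1_weights optional per-coefficient weights entering
#'   \eqn{\lambda_{max}}; infinite (excluded) entries are skipped.
#' @return decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, y, alpha = 1, n_lambda = 50L, ratio = 1e-3,
                        l1_weights = 1) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  w <- l1_weights
  if (length(w) == 1L) w <- rep(w, ncol(X))
  g <- abs(drop(crossprod(X, y - mean(y)))) / nrow(X)
  denom <- pmax(alpha, 0.001) * w
  r <- g / denom
  r <- r[is.finite(r) & denom > 0]
  if (!length(r)) stop("no penalized coordinate with a finite weight")
  # tiny relative guard so a fit at exactly lambda_max is empty regardless of
  # floating-point summation order in the first gradient evaluation
  lmax <- max(r) * (1 + 1e-9)
  if (n_lambda == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

#' Unpenalized logistic maximum-likelihood estimate
#'
#' IRLS fit via [stats::glm.fit()]; when the fit fails to converge or shows
#' signs of separation (any coefficient magnitude above `10^3`, or fitted
#' probabilities numerically at 0 or 1), the
#' estimate is recomputed with a small ridge penalty `stabilizer` and the
#' result is flagged.
#'
#' @param X,y data; `y` must contain both classes.
#' @param stabilizer ridge scale of the fallback refit.
#' @return list with `beta0`, `beta`, and `stabilized` flag.
#' @export
mle_logistic <- function(X, y, stabilizer = 1e-4) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  cf <- fit$coefficients
  pr <- fit$fitted.values
  ok <- fit$converged && all(is.finite(cf)) && max(abs(cf[-1])) <= 1e3 &&
    !any(pr < 1e-8 | pr > 1 - 1e-8)
  if (ok) {
    return(list(beta0 = unname(cf[1]), beta = unname(cf[-1]),
                stabilized = FALSE))
  }
  ridge <- fit_penalized_logistic(X, y,
                                  penalty_spec(lambda1 = stabilizer, alpha = 0),
                                  method = "ridge_stabilized_mle")
  list(beta0 = ridge$beta0, beta = ridge$beta, stabilized = TRUE)
}

#' KKT residuals of a fitted penalized logistic model
#'
#' Subgradient certificate for the solver's stationary point: for each
#' non-zero coefficient the smooth gradient plus the L1 subgradient must be
#' zero; for each zero coefficient the smooth gradient must lie within the
#' L1 threshold. Returns the worst violation, which should be below the
#' solver tolerance for a converged fit.
#'
#' @param X,y data the fit was produced from.
#' @param fit a `fit_result`.
#' @param penalty the realized [penalty_spec()].
#' @return scalar: maximum KKT violation.
#' @export
kkt_violation <- function(X, y, fit, penalty) {
  X <- as.matrix(X)
  p <- ncol(X)
  w <- expand_weights(penalty, p)
  eta <- drop(fit$beta0 + X %*% fit$beta)
  pr <- stats::plogis(eta)
  g <- drop(crossprod(X, pr - y)) / nrow(X) +
    penalty$lambda1 * (1 - penalty$alpha) * w * fit$beta
  if (penalty$lambda2 > 0)
    g <- g + 2 * penalty$lambda2 * drop(penalty$fusion_matrix %*% fit$beta)
  thr <- penalty$lambda1 * penalty$alpha * w
  viol <- numeric(p)
  nz <- fit$beta != 0
  viol[nz] <- abs(g[nz] + thr[nz] * sign(fit$beta[nz]))
  viol[!nz] <- pmax(abs(g[!nz]) - thr[!nz], 0)
  viol[is.infinite(w)] <- 0 # excluded coordinates carry no condition
  gi <- abs(mean(pr - y)) # intercept stationarity
  max(c(viol, gi))
}
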