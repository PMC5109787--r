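test_that("null model objective is log 2 and the penalty vanishes at zero", {
  d <- toy_logistic(40, c(1, -1), seed = 3)
  pen <- penalty_spec(lambda1 = 0.7, alpha = 0.4)
  expect_equal(penalized_objective(d$X, d$y, 0, c(0, 0), pen), log(2),
               tolerance = 1e-12)
})

test_that("elastic-net penalty at alpha = 1 equals the plain LASSO penalty", {
  d <- toy_logistic(30, c(0.5, -0.3, 0.2), seed = 5)
  beta <- c(0.4, -0.2, 0.1)
  lam <- 0.3
  en <- penalized_objective(d$X, d$y, 0.1, beta,
                            penalty_spec(lambda1 = lam, alpha = 1))
  eta <- 0.1 + d$X %*% beta
  direct <- -mean(d$y * eta - log(1 + exp(eta))) + lam * sum(abs(beta))
  expect_equal(en, direct, tolerance = 1e-12)
})

test_that("objective matches an independent hand evaluation on a fixture", {
  X <- matrix(c(0.3, -1.2, 0.8, 1.1, 0.4, -0.5), 3, 2)
  y <- c(1, 0, 1)
  beta <- c(0.5, -0.5); beta0 <- 0.2
  pen <- penalty_spec(lambda1 = 0.1, alpha = 0.6, l1_weights = c(1, 2))
  eta <- beta0 + X %*% beta
  expected <- -sum(y * eta - log(1 + exp(eta))) / 3 +
    0.1 * sum(c(1, 2) * (0.5 * 0.4 * beta^2 + 0.6 * abs(beta)))
  expect_equal(penalized_objective(X, y, beta0, beta, pen), expected,
               tolerance = 1e-12)
})

test_that("an infinite weight with a non-zero coefficient yields +Inf", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  pen <- penalty_spec(lambda1 = 0.1, l1_weights = c(1, Inf))
  expect_identical(penalized_objective(X, y, 0, c(0.2, 0.3), pen), Inf)
  expect_true(is.finite(penalized_objective(X, y, 0, c(0.2, 0), pen)))
})

test_that("full shrinkage at lambda_max gives the intercept-only model", {
  d <- toy_logistic(150, c(0.8, -0.5, 0.3), beta0 = -0.3, seed = 11)
  lmax <- lambda_path(d$X, d$y, alpha = 1, n_lambda = 1)
  fit <- fit_penalized_logistic(d$X, d$y, penalty_spec(lambda1 = lmax))
  expect_length(fit$support, 0)
  expect_equal(fit$beta0, qlogis(mean(d$y)), tolerance = 1e-5)
  # and just below lambda_max the most correlated coordinate activates
  fit2 <- fit_penalized_logistic(d$X, d$y, penalty_spec(lambda1 = 0.95 * lmax))
  expect_gt(length(fit2$support), 0)
})

test_that("unpenalized fit matches glm to 1e-6", {
  d <- toy_logistic(200, c(1, -0.7), beta0 = 0.2, seed = 7)
  fit <- fit_penalized_logistic(d$X, d$y, penalty_spec(lambda1 = 0))
  g <- glm(d$y ~ d$X, family = binomial)
  expect_equal(c(fit$beta0, fit$beta), unname(coef(g)), tolerance = 1e-6)
})

test_that("LASSO, elastic-net, and ridge fits match glmnet", {
  skip_if_not_installed("glmnet")
  d <- toy_logistic(300, c(1, -0.8, 0.5, 0, 0), rho = 0.3, seed = 13)
  cases <- list(list(alpha = 1, lambda = 0.03),
                list(alpha = 0.5, lambda = 0.05),
                list(alpha = 0, lambda = 0.1))
  for (cs in cases) {
    f <- fit_penalized_logistic(d$X, d$y,
                                penalty_spec(lambda1 = cs$lambda,
                                             alpha = cs$alpha))
    g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = cs$alpha,
                        lambda = cs$lambda, standardize = FALSE,
                        thresh = 1e-12)
    expect_equal(c(f$beta0, f$beta), as.numeric(coef(g)), tolerance = 2e-5)
  }
})

test_that("KKT certificate holds across the penalty family", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(60:200, 1); p <- sample(3:10, 1)
    d <- toy_logistic(n, rnorm(p, sd = 0.6), rho = runif(1, 0, 0.6),
                      seed = 100 + rep)
    if (length(unique(d$y)) < 2) next
    fw <- if (p >= 2) make_fusion_matrix(d$X, gamma = 1) else NULL
    pens <- list(
      penalty_spec(lambda1 = 0.05, alpha = 1),
      penalty_spec(lambda1 = 0.05, alpha = 0.3),
      penalty_spec(lambda1 = 0.08, alpha = 1,
                   l1_weights = runif(p, 0.3, 3)),
      penalty_spec(lambda1 = 0.04, alpha = 1, lambda2 = 0.5,
                   fusion_matrix = fw$fusion_matrix))
    for (pen in pens) {
      f <- fit_penalized_logistic(d$X, d$y, pen)
      expect_true(f$converged)
      expect_lt(kkt_violation(d$X, d$y, f, pen), 1e-6)
    }
  }
})

test_that("solver agrees with an independent proximal-gradient oracle", {
  set.seed(31)
  d <- toy_logistic(120, c(0.9, -0.6, 0.4, 0, 0.2), rho = 0.4, seed = 17)
  fw <- make_fusion_matrix(d$X, gamma = 2)
  pens <- list(penalty_spec(lambda1 = 0.04, alpha = 1),
               penalty_spec(lambda1 = 0.06, alpha = 0.4),
               penalty_spec(lambda1 = 0.05, alpha = 1,
                            l1_weights = c(0.5, 2, 1, 4, 1)),
               penalty_spec(lambda1 = 0.03, alpha = 1, lambda2 = 0.3,
                            fusion_matrix = fw$fusion_matrix))
  for (pen in pens) {
    f <- fit_penalized_logistic(d$X, d$y, pen)
    o <- ista_oracle(d$X, d$y, pen)
    expect_equal(c(f$beta0, f$beta), c(o$beta0, o$beta), tolerance = 1e-4)
  }
})

test_that("solver agrees with exhaustive lattice search at p = 2", {
  d <- toy_logistic(40, c(0.8, -0.5), beta0 = 0.2, seed = 23)
  pens <- list(penalty_spec(lambda1 = 0.05, alpha = 1),
               penalty_spec(lambda1 = 0.08, alpha = 0.5))
  for (pen in pens) {
    f <- fit_penalized_logistic(d$X, d$y, pen)
    o <- lattice_oracle(d$X, d$y, pen)
    expect_equal(c(f$beta0, f$beta), c(o$beta0, o$beta), tolerance = 2e-3)
  }
})

test_that("converged fits do not exceed the zero-initialized objective", {
  d <- toy_logistic(100, c(0.7, -0.4, 0.3), seed = 29)
  pen <- penalty_spec(lambda1 = 0.02, alpha = 0.8)
  f <- fit_penalized_logistic(d$X, d$y, pen)
  expect_lte(f$objective,
             penalized_objective(d$X, d$y, 0, rep(0, 3), pen))
})

test_that("fusion matrix reproduces the printed 2x2 example and formulas", {
  # two standardized columns with sample correlation ~0.5
  set.seed(41)
  z <- rnorm(4000); x2 <- 0.5 * z + sqrt(1 - 0.25) * rnorm(4000)
  X <- cbind(z, x2)
  fw <- make_fusion_matrix(X, gamma = 1)
  rho <- fw$rho_matrix[1, 2]
  w12 <- abs(rho) / (1 - abs(rho))
  expect_equal(fw$weight_matrix[1, 2], w12, tolerance = 1e-12)
  expect_equal(fw$fusion_matrix,
               matrix(c(w12, -w12, -w12, w12) / 2, 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # equal coefficients on a positively correlated pair: no fusion penalty
  expect_equal(drop(t(c(1, 1)) %*% fw$fusion_matrix %*% c(1, 1)), 0,
               tolerance = 1e-12)
})

test_that("fusion quadratic form equals brute-force pairwise summation", {
  set.seed(43)
  X <- generate_predictors(200, 6, 0.5, seed = 47)
  fw <- make_fusion_matrix(X, gamma = 2.5)
  for (i in 1:100) {
    b <- rnorm(6)
    expect_equal(drop(t(b) %*% fw$fusion_matrix %*% b),
                 fusion_bruteforce(b, fw), tolerance = 1e-10)
  }
})

test_that("exactly uncorrelated columns give a zero fusion matrix", {
  X <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  fw <- make_fusion_matrix(X, gamma = 1)
  expect_equal(fw$fusion_matrix, matrix(0, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("constant columns are handled with a warning, correlation zero", {
  X <- cbind(rnorm(50), rep(1, 50))
  expect_warning(fw <- make_fusion_matrix(X, gamma = 1), "constant")
  expect_equal(fw$weight_matrix[1, 2], 0)
})

test_that("lambda path has n_lambda points and a valid lambda_max", {
  d <- toy_logistic(150, c(1, -0.6, 0.4), seed = 53)
  expect_length(lambda_path(d$X, d$y, 1, n_lambda = 1), 1)
  lams <- lambda_path(d$X, d$y, 1, n_lambda = 20, ratio = 0.01)
  expect_length(lams, 20)
  expect_equal(lams[20], lams[1] * 0.01, tolerance = 1e-12)
  # brute scan: every lambda above lambda_max keeps the model empty,
  # shortly below it the model is non-empty
  for (mult in c(1.2, 1.05, 1.0)) {
    f <- fit_penalized_logistic(d$X, d$y,
                                penalty_spec(lambda1 = mult * lams[1]))
    expect_length(f$support, 0)
  }
  f <- fit_penalized_logistic(d$X, d$y,
                              penalty_spec(lambda1 = 0.9 * lams[1]))
  expect_gt(length(f$support), 0)
  expect_error(lambda_path(d$X, rep(1, 150)), "both classes")
})

test_that("infinite L1 weights exclude coordinates from the solve", {
  d <- toy_logistic(200, c(1, 1), rho = 0.2, seed = 59)
  pen <- penalty_spec(lambda1 = 0.01, l1_weights = c(1, Inf))
  f <- fit_penalized_logistic(d$X, d$y, pen)
  expect_identical(f$beta[2], 0)
  expect_true(1 %in% f$support)
})

test_that("single-class outcomes return a flagged intercept-only fit", {
  X <- matrix(rnorm(40), 20, 2)
  expect_warning(f <- fit_penalized_logistic(X, rep(1, 20),
                                             penalty_spec(lambda1 = 0.1)),
                 "single class")
  expect_length(f$support, 0)
})

test_that("logistic MLE is consistent, flags separation, recovers truth", {
  # null model: coefficients near zero
  d <- toy_logistic(5000, rep(0, 5), seed = 61)
  m <- mle_logistic(d$X, d$y)
  expect_true(all(abs(m$beta) < 0.1))
  expect_false(m$stabilized)
  # perfectly separable toy: stabilized fallback, finite output
  Xs <- matrix(c(-2, -1, 1, 2), 4, 1)
  ys <- c(0, 0, 1, 1)
  ms <- mle_logistic(Xs, ys)
  expect_true(ms$stabilized)
  expect_true(all(is.finite(c(ms$beta0, ms$beta))))
  # parameter recovery within 3 standard errors
  d2 <- toy_logistic(1000, c(1, -1), seed = 67)
  m2 <- mle_logistic(d2$X, d2$y)
  g <- glm(d2$y ~ d2$X, family = binomial)
  se <- sqrt(diag(vcov(g)))[-1]
  expect_true(all(abs(m2$beta - c(1, -1)) < 3 * se))
  expect_error(mle_logistic(d2$X, rep(0, 1000)), "both classes")
})
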