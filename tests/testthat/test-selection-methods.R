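# Small-scale tuning plan shared by these tests (defined in helper-oracles.R):
# 5 folds, 25-point lambda path, ratio 1e-2, fold_seed 99.

test_that("tuning plan validates its grids", {
  p <- tuning_plan()
  expect_equal(p$n_folds, 10L)
  expect_equal(p$alpha_grid, seq(0, 1, by = 0.1))
  expect_equal(p$gamma_grid, c(0.5, 1, 2.5, 5, 25))
  expect_equal(p$v_exponent, 1)
  expect_error(tuning_plan(n_folds = 1), "n_folds")
  expect_error(tuning_plan(v_exponent = 0), "v_exponent")
})

test_that("folds are stratified, deterministic, and guarded", {
  y <- rep(c(0, 1), c(80, 20))
  f <- make_cv_folds(y, 10, seed = 3)
  expect_identical(f, make_cv_folds(y, 10, seed = 3))
  # every fold contains both classes
  for (k in 1:10) expect_equal(sort(unique(y[f == k])), c(0, 1))
  expect_equal(unname(table(f[y == 1])), rep(2L, 10), ignore_attr = TRUE)
  expect_error(make_cv_folds(rep(c(0, 1), c(95, 5)), 10, 1), "n_folds")
})

test_that("a single-candidate grid is returned with the argmin contract", {
  d <- toy_logistic(200, c(1.2, -0.8, 0, 0), rho = 0.2, seed = 101)
  tuned <- cv_tune(d$X, d$y, "lasso", fast_plan())
  expect_equal(tuned$alpha, 1)
  expect_equal(tuned$lambda2, 0)
  # chosen deviance is the table minimum, achieved at the chosen lambda
  expect_equal(tuned$deviance, min(tuned$cv_table$cv_deviance))
  at_min <- tuned$cv_table[tuned$cv_table$cv_deviance == tuned$deviance, ]
  expect_true(tuned$lambda %in% at_min$lambda)
  # ties break to the largest lambda
  expect_equal(tuned$lambda, max(at_min$lambda))
})

test_that("strong signal pulls the chosen lambda below lambda_max", {
  for (seed in c(11, 12, 13)) {
    d <- toy_logistic(500, c(3), seed = seed)
    tuned <- cv_tune(d$X, d$y, "lasso", fast_plan())
    lmax <- lambda_path(d$X, d$y, 1, n_lambda = 1)
    expect_lt(tuned$lambda, lmax)
  }
})

test_that("adaptive weights follow the 1/|beta|^v formula", {
  expect_equal(adaptive_weights(c(2, 0.5), v = 1), c(0.5, 2))
  expect_equal(adaptive_weights(c(2, 0.5), v = 2), c(0.25, 4))
  expect_identical(adaptive_weights(c(1, 0), v = 1)[2], Inf)
  expect_error(adaptive_weights(c(1, 2), v = 0), "v > 0")
})

test_that("an exactly-zero pilot coefficient excludes the variable", {
  d <- toy_logistic(200, c(1.5, 0.8, 0.4), rho = 0.1, seed = 107)
  w <- c(1, Inf, 1)
  fit <- lassosim:::fit_weighted_l1(d$X, d$y, w, fast_plan(), "adaptive_lasso")
  expect_identical(fit$beta[2], 0)
  expect_false(2 %in% fit$support)
})

test_that("adaptive lasso flags a stabilized pilot on separable data", {
  set.seed(109)
  # x1 perfectly separates the classes
  X <- cbind(c(seq(-3, -0.5, length.out = 30), seq(0.5, 3, length.out = 30)),
             matrix(rnorm(120), 60, 2))
  y <- rep(c(0, 1), each = 30)
  fit <- fit_adaptive_lasso(X, y, fast_plan())
  expect_true(fit$tuning$stabilized)
  expect_true(all(is.finite(c(fit$beta0, fit$beta))))
  expect_true(1 %in% fit$support)
})

test_that("elastic net with alpha grid {1} equals the lasso fit", {
  d <- toy_logistic(250, c(0.9, -0.6, 0.3, 0, 0), rho = 0.3, seed = 113)
  fl <- fit_lasso(d$X, d$y, fast_plan())
  fe <- fit_elastic_net(d$X, d$y, fast_plan(alpha_grid = 1))
  expect_identical(fe$beta, fl$beta)
  expect_identical(fe$beta0, fl$beta0)
  expect_equal(fe$penalty$lambda1, fl$penalty$lambda1)
})

test_that("elastic net with alpha grid {0} keeps every coefficient non-zero", {
  d <- toy_logistic(250, c(0.9, -0.6, 0.3, 0, 0), rho = 0.3, seed = 113)
  fe <- fit_elastic_net(d$X, d$y, fast_plan(alpha_grid = 0))
  expect_true(all(fe$beta != 0))
  expect_equal(fe$penalty$alpha, 0)
})

test_that("elastic net keeps a correlated pair together more often than lasso", {
  en_both <- la_both <- 0
  for (r in 1:50) {
    X <- cbind(generate_predictors(150, 2, 0.9, seed = r),
               generate_predictors(150, 2, 0, seed = r + 500))
    y <- generate_outcome(X, list(beta0 = 0, beta = c(0.35, 0.35, 0, 0)),
                          seed = r + 1500)
    if (min(table(y)) < 5) next
    la_both <- la_both + all(c(1, 2) %in% fit_lasso(X, y, fast_plan())$support)
    en_both <- en_both + all(c(1, 2) %in%
                               fit_elastic_net(X, y, fast_plan())$support)
  }
  expect_gt(en_both, la_both)
})

test_that("iterated lasso support is a subset of the stage-1 lasso support", {
  for (seed in c(131, 137, 139)) {
    d <- toy_logistic(300, c(0.8, -0.5, 0.3, 0.2, rep(0, 6)), rho = 0.2,
                      seed = seed)
    if (min(table(d$y)) < 5) next
    s1 <- fit_lasso(d$X, d$y, fast_plan())$support
    il <- fit_iterated_lasso(d$X, d$y, fast_plan())
    expect_true(all(il$support %in% s1))
  }
})

test_that("an empty stage-1 support yields an intercept-only iterated lasso", {
  # null data where CV-tuned lasso selects nothing (verified fixture seed)
  d <- toy_logistic(100, rep(0, 8), seed = 7002)
  s1 <- fit_lasso(d$X, d$y, fast_plan())
  expect_length(s1$support, 0)
  il <- fit_iterated_lasso(d$X, d$y, fast_plan())
  expect_length(il$support, 0)
  expect_equal(il$beta0, qlogis(mean(d$y)), tolerance = 1e-8)
  expect_equal(il$method, "iterated_lasso")
})

test_that("sparsity ordering IL <= LASSO <= EN holds on weak-signal data", {
  sel <- matrix(NA_real_, 50, 3)
  for (r in 1:50) {
    d <- toy_logistic(300, c(0.1, -0.1, 0.2, 0.3, 0.4, rep(0, 15)),
                      beta0 = -0.4, rho = 0.2, seed = 2000 + r)
    if (min(table(d$y)) < 5) next
    sel[r, 1] <- length(fit_iterated_lasso(d$X, d$y, fast_plan())$support)
    sel[r, 2] <- length(fit_lasso(d$X, d$y, fast_plan())$support)
    sel[r, 3] <- length(fit_elastic_net(d$X, d$y, fast_plan())$support)
  }
  med <- apply(sel, 2, median, na.rm = TRUE)
  expect_lte(med[1], med[2])
  expect_lte(med[2], med[3])
  # paired one-sided test at the 1% level: IL is sparser than LASSO
  p <- suppressWarnings(
    wilcox.test(sel[, 1], sel[, 2], paired = TRUE,
                alternative = "less")$p.value)
  expect_lt(p, 0.01)
})

test_that("bootstrap aggregation applies the 75% threshold arithmetic", {
  beta_mat <- rbind(c(1.0, 0.5, 0.0),
                    c(0.8, 0.0, 0.2),
                    c(1.2, 0.7, 0.0),
                    c(0.9, 0.6, 0.3))
  agg <- bootstrap_aggregate(c(0.1, 0.2, 0.3, 0.4), beta_mat)
  expect_equal(agg$selection_frequency, c(1.0, 0.75, 0.5))
  expect_equal(agg$selected, c(1L, 2L))
  expect_equal(agg$median_beta, c(median(beta_mat[, 1]),
                                  median(beta_mat[, 2]), 0))
  expect_equal(agg$median_beta0, 0.25)
  expect_equal(agg$n_boot, 4)
  # nothing over threshold: all coefficients zero
  none <- bootstrap_aggregate(1:4, matrix(c(1, 0, 0, 0), 4, 1))
  expect_length(none$selected, 0)
  expect_equal(none$median_beta, 0)
})

test_that("identical bootstrap fits aggregate to the common fit", {
  b <- c(0.4, 0, -0.2)
  beta_mat <- matrix(rep(b, each = 6), 6, 3)
  agg <- bootstrap_aggregate(rep(-0.1, 6), beta_mat)
  expect_equal(agg$selected, c(1L, 3L))
  expect_equal(agg$median_beta, b)
  expect_equal(agg$median_beta0, -0.1)
})

test_that("a dominant signal reaches bootstrap selection frequency 1", {
  d <- toy_logistic(500, c(2, 0, 0, 0, 0), seed = 31)
  bl <- fit_bl75(d$X, d$y, fast_plan(), n_boot = 100)
  expect_equal(bl$aggregate$selection_frequency[1], 1.0)
  expect_true(1 %in% bl$aggregate$selected)
  expect_true(1 %in% bl$fit$support)
  expect_equal(bl$fit$method, "bl75")
  # the reported fit carries the aggregate's median coefficients
  expect_identical(bl$fit$beta, bl$aggregate$median_beta)
})

test_that("weighted fusion with lambda2 grid {0} equals the lasso fit", {
  d <- toy_logistic(250, c(0.8, -0.5, 0.4, 0, 0), rho = 0.4, seed = 149)
  fl <- fit_lasso(d$X, d$y, fast_plan())
  fw <- fit_weighted_fusion(d$X, d$y, fast_plan(lambda2_grid = 0))
  expect_identical(fw$beta, fl$beta)
  expect_identical(fw$beta0, fl$beta0)
})

test_that("a zero fusion matrix reduces the fused fit to the lasso fit", {
  d <- toy_logistic(200, c(0.9, -0.6), rho = 0, seed = 151)
  pen_l <- penalty_spec(lambda1 = 0.04)
  pen_f <- penalty_spec(lambda1 = 0.04, lambda2 = 0.7,
                        fusion_matrix = matrix(0, 2, 2))
  fl <- fit_penalized_logistic(d$X, d$y, pen_l)
  ff <- fit_penalized_logistic(d$X, d$y, pen_f)
  expect_equal(c(ff$beta0, ff$beta), c(fl$beta0, fl$beta), tolerance = 1e-9)
})

test_that("fusion draws a correlated true pair's coefficients together", {
  wins <- 0; total <- 0
  for (r in 1:50) {
    X <- cbind(generate_predictors(200, 2, 0.8, seed = 4000 + r),
               generate_predictors(200, 4, 0, seed = 4500 + r))
    y <- generate_outcome(X, list(beta0 = 0, beta = c(0.6, 0.6, rep(0, 4))),
                          seed = 5000 + r)
    if (min(table(y)) < 5) next
    pw <- fast_plan(gamma_grid = c(1, 5),
                    lambda2_grid = 10^seq(-2, 1, length.out = 4))
    fw <- fit_weighted_fusion(X, y, pw)
    fl <- fit_lasso(X, y, pw)
    total <- total + 1
    wins <- wins + (abs(fw$beta[1] - fw$beta[2]) <=
                      abs(fl$beta[1] - fl$beta[2]))
  }
  expect_gte(wins / total, 0.8)
})

test_that("the method registry is deterministic for all six selectors", {
  d <- toy_logistic(200, c(1, -0.7, 0.4, 0, 0, 0), rho = 0.3, seed = 157)
  for (m in selection_methods()) {
    a <- fit_method(m, d$X, d$y, fast_plan(), n_boot = 5)
    b <- fit_method(m, d$X, d$y, fast_plan(), n_boot = 5)
    expect_identical(a$beta, b$beta)
    expect_identical(a$beta0, b$beta0)
    expect_equal(a$method, m)
    # every returned fit satisfies the KKT certificate for its penalty
    if (m != "bl75") # the median-coefficient model is not a penalized optimum
      expect_lt(kkt_violation(d$X, d$y, a, a$penalty), 1e-5)
  }
  expect_error(fit_method("ridge", d$X, d$y), "unknown method")
})
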