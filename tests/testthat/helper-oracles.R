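# Independent oracles used to validate the coordinate-descent solver.

# Proximal-gradient (FISTA) solver for the same objective; an independent
# algorithm family from IRLS/coordinate descent. Intercept handled as an
# unpenalized coordinate.
ista_oracle <- function(X, y, penalty, iters = 50000) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  w <- penalty$l1_weights
  if (length(w) == 1L) w <- rep(w, p)
  keep <- is.finite(w)
  Xa <- cbind(1, X)
  L <- 0.25 * max(eigen(crossprod(Xa) / n, symmetric = TRUE,
                        only.values = TRUE)$values)
  L <- L + penalty$lambda1 * (1 - penalty$alpha) * max(c(w[keep], 0))
  if (penalty$lambda2 > 0)
    L <- L + 2 * penalty$lambda2 *
      max(eigen(penalty$fusion_matrix, symmetric = TRUE,
                only.values = TRUE)$values)
  step <- 1 / L
  th <- rep(0, p + 1) # (beta0, beta)
  zth <- th; tk <- 1
  l1 <- c(0, penalty$lambda1 * penalty$alpha * ifelse(keep, w, 0))
  for (it in seq_len(iters)) {
    b <- zth[-1]; b[!keep] <- 0
    eta <- drop(Xa %*% c(zth[1], b))
    gr <- drop(crossprod(Xa, stats::plogis(eta) - y)) / n
    gr[-1] <- gr[-1] + penalty$lambda1 * (1 - penalty$alpha) * ifelse(keep, w, 0) * b
    if (penalty$lambda2 > 0)
      gr[-1] <- gr[-1] + 2 * penalty$lambda2 * drop(penalty$fusion_matrix %*% b)
    u <- c(zth[1], b) - step * gr
    thn <- sign(u) * pmax(abs(u) - step * l1, 0)
    thn[-1][!keep] <- 0
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zth <- thn + ((tk - 1) / tn) * (thn - th)
    if (max(abs(thn - th)) < 1e-11 && it > 100) { th <- thn; break }
    th <- thn; tk <- tn
  }
  list(beta0 = th[1], beta = th[-1])
}

# Two-stage exhaustive lattice search over (beta0, beta1, beta2) for p = 2:
# a coarse pass over a cube, then a fine pass (step `fine`) around the
# coarse argmin. Evaluates the penalized objective at every lattice point.
lattice_oracle <- function(X, y, penalty, lim = 2, coarse = 0.05,
                           fine = 0.002) {
  stopifnot(ncol(X) == 2)
  best_over <- function(b0s, b1s, b2s) {
    G <- as.matrix(expand.grid(b0 = b0s, b1 = b1s, b2 = b2s))
    Xa <- cbind(1, X)
    best <- NULL
    for (chunk in split(seq_len(nrow(G)), ceiling(seq_len(nrow(G)) / 50000))) {
      Gc <- G[chunk, , drop = FALSE]
      eta <- Xa %*% t(Gc)
      nll <- -colMeans(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
      pen <- penalty$lambda1 *
        ((0.5 * (1 - penalty$alpha)) * (Gc[, 2]^2 + Gc[, 3]^2) +
           penalty$alpha * (abs(Gc[, 2]) + abs(Gc[, 3])))
      if (penalty$lambda2 > 0) {
        M <- penalty$fusion_matrix
        pen <- pen + penalty$lambda2 *
          (M[1, 1] * Gc[, 2]^2 + 2 * M[1, 2] * Gc[, 2] * Gc[, 3] +
             M[2, 2] * Gc[, 3]^2)
      }
      obj <- nll + pen
      i <- which.min(obj)
      if (is.null(best) || obj[i] < best$value)
        best <- list(value = obj[i], par = Gc[i, ])
    }
    best
  }
  ax <- seq(-lim, lim, by = coarse)
  b <- best_over(ax, ax, ax)
  refine <- function(center) seq(center - 1.5 * coarse, center + 1.5 * coarse,
                                 by = fine)
  b <- best_over(refine(b$par[1]), refine(b$par[2]), refine(b$par[3]))
  list(beta0 = unname(b$par[1]), beta = unname(b$par[2:3]), value = b$value)
}

# Brute-force AUC by exhaustive case-control pair comparison.
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# Brute-force fusion penalty J(beta) as the explicit pairwise sum.
fusion_bruteforce <- function(beta, fw) {
  p <- length(beta)
  s <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    s <- s + fw$weight_matrix[i, j] *
      (beta[i] - fw$sign_matrix[i, j] * beta[j])^2
  s / p
}

# Small logistic dataset with a known model.
toy_logistic <- function(n, beta, beta0 = 0, rho = 0, seed = 1) {
  X <- generate_predictors(n, length(beta), rho, seed)
  y <- generate_outcome(X, list(beta0 = beta0, beta = beta), seed + 1000)
  list(X = X, y = y)
}

# Reduced-size tuning plan for fast unit tests.
fast_plan <- function(...) {
  tuning_plan(n_folds = 5L, n_lambda = 25L, lambda_ratio = 1e-2,
              fold_seed = 99L, ...)
}
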