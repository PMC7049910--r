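smooth_sample <- function(P = 42, Tn = 21, n_basis = 3, noise = 0.01,
                          seed = 1) {
  set.seed(seed)
  tg <- seq(0, 1, length.out = Tn)
  B <- vapply(seq_len(n_basis), function(k)
    sin(pi * k * tg) + 0.3 * tg^k, numeric(Tn))
  Y <- matrix(stats::rnorm(P * n_basis), P, n_basis) %*% t(B)
  Y + stats::rnorm(P * Tn, sd = noise * stats::sd(Y))
}

test_that("centering removes the pointwise mean", {
  X <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(center_sample(X), matrix(0, 4, 3))
  A <- matrix(c(1, -1, 2, -2), 2, 2)
  expect_equal(center_sample(A), A)             # rows (a, -a) unchanged
  set.seed(401)
  R <- matrix(stats::rnorm(60), 6, 10)
  expect_lt(max(abs(colMeans(center_sample(R)))), 1e-12)
  expect_error(center_sample(R[1, , drop = FALSE]), "two subjects")
})

test_that("quadrature weights are positive and sum to the duration", {
  tg <- seq(0, 24.33, length.out = 21)
  w <- trapezoid_weights(tg)
  expect_true(all(w > 0))
  expect_equal(sum(w), 24.33)
})

test_that("rank-1 data yields a single mode proportional to the factor", {
  tg <- seq(0, 1, length.out = 15)
  f <- sin(2 * pi * tg)
  cvec <- c(-2, -1, 0, 1, 2)
  X <- outer(cvec, f)
  fit <- univariate_fpca(X, times = tg, M = 2)
  expect_lt(fit$eigenvalues[2] / fit$eigenvalues[1], 1e-12)
  # first eigenfunction proportional to f, scores proportional to c_i
  corr <- abs(stats::cor(fit$eigenfunctions[, 1], f))
  expect_gt(corr, 1 - 1e-10)
  expect_gt(abs(stats::cor(fit$scores[, 1], cvec)), 1 - 1e-10)
})

test_that("with uniform weights FPCA equals sqrt(dt)-scaled PCA", {
  set.seed(402)
  P <- 20; Tn <- 15; dt <- 0.37
  X <- matrix(stats::rnorm(P * Tn), P, Tn)
  fit <- univariate_fpca(X, times = (0:(Tn - 1)) * dt, M = 5,
                         weights = rep(dt, Tn))
  pc <- stats::prcomp(X, center = TRUE)
  for (k in 1:5) {
    expect_lt(min(max(abs(fit$scores[, k] - pc$x[, k] * sqrt(dt))),
                  max(abs(fit$scores[, k] + pc$x[, k] * sqrt(dt)))),
              1e-8)
    expect_lt(min(max(abs(fit$eigenfunctions[, k] -
                            pc$rotation[, k] / sqrt(dt))),
                  max(abs(fit$eigenfunctions[, k] +
                            pc$rotation[, k] / sqrt(dt)))),
              1e-8)
  }
  # score variance equals the eigenvalue; norm is 1 under the weights
  expect_equal(apply(fit$scores, 2, stats::var),
               fit$eigenvalues[1:5], tolerance = 1e-10)
  norms <- colSums(rep(dt, Tn) * fit$eigenfunctions^2)
  expect_equal(unname(norms), rep(1, 5))
  # eigenfunctions mutually orthogonal under the quadrature product
  G <- t(fit$eigenfunctions) %*% (rep(dt, Tn) * fit$eigenfunctions)
  expect_lt(max(abs(G - diag(5))), 1e-10)
})

test_that("five components capture smooth low-rank trajectories", {
  fit <- univariate_fpca(smooth_sample(seed = 403),
                         times = seq(0, 1, length.out = 21), M = 5)
  expect_gte(explained_variance(fit), 0.99)
  expect_error(univariate_fpca(matrix(0, 3, 4), M = 5), "exceeds")
})

test_that("M-term reconstruction error decreases and vanishes at full rank", {
  set.seed(404)
  P <- 8; Tn <- 10
  X <- matrix(stats::rnorm(P * Tn), P, Tn)
  tg <- seq(0, 1, length.out = Tn)
  w <- trapezoid_weights(tg)
  errs <- vapply(seq_len(P - 1), function(M) {
    f <- univariate_fpca(X, times = tg, M = M, weights = w)
    recon <- sweep(f$scores %*% t(f$eigenfunctions), 2, f$mean, "+")
    sqrt(sum((X - recon)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-10))
  expect_lt(errs[P - 1], 1e-8)
  # variance bookkeeping: sum of score variances <= total weighted var
  f <- univariate_fpca(X, times = tg, M = P - 1, weights = w)
  tot <- sum(w * apply(X, 2, stats::var))
  expect_lte(sum(apply(f$scores, 2, stats::var)), tot + 1e-10)
})

test_that("score assembly stacks per-element blocks in order", {
  set.seed(405)
  X <- matrix(stats::rnorm(60), 12, 5)
  f1 <- univariate_fpca(X, M = 3)
  expect_equal(assemble_scores(list(f1)), f1$scores, ignore_attr = TRUE)
  f2 <- univariate_fpca(matrix(stats::rnorm(60), 12, 5), M = 3)
  Xi <- assemble_scores(list(f1, f2))
  expect_identical(ncol(Xi), 6L)
  expect_equal(Xi[, 1:3], f1$scores)
  expect_equal(attr(Xi, "block"), rep(1:2, each = 3))
  f_bad <- univariate_fpca(matrix(stats::rnorm(50), 10, 5), M = 3)
  expect_error(assemble_scores(list(f1, f_bad)), "inconsistent")
  # 128 elements at M = 5 give 640 columns
  expect_identical(128L * 5L, 640L)
})

test_that("first-mode scores match eigen identities and an independent solver", {
  set.seed(406)
  Xi <- matrix(stats::rnorm(140), 20, 7)
  fm <- first_mode_scores(Xi)
  expect_equal(mean(fm$scores), 0, tolerance = 1e-12)
  ev <- eigen(stats::cov(scale(Xi, scale = FALSE)))$values
  expect_equal(stats::var(fm$scores), ev[1], tolerance = 1e-10)
  # independent oracle: SVD of the centred matrix
  Xc <- scale(Xi, scale = FALSE)
  sv <- svd(Xc)
  s_oracle <- sv$u[, 1] * sv$d[1]
  expect_lt(min(max(abs(fm$scores - s_oracle)),
                max(abs(fm$scores + s_oracle))), 1e-10)
  # one varying column: scores equal that column, centred
  Z <- matrix(1, 10, 4)
  Z[, 3] <- stats::rnorm(10)
  fz <- first_mode_scores(Z)
  tgt <- Z[, 3] - mean(Z[, 3])
  expect_lt(min(max(abs(fz$scores - tgt)), max(abs(fz$scores + tgt))),
            1e-10)
  expect_error(first_mode_scores(matrix(1, 5, 3)), "degenerate")
})

test_that("element reordering permutes blocks but leaves first-mode scores unchanged", {
  set.seed(407)
  mats <- lapply(1:4, function(j) matrix(stats::rnorm(12 * 9), 12, 9))
  fit1 <- mfpca(mats, M = 3)
  fit2 <- mfpca(mats[c(3, 1, 4, 2)], M = 3)
  expect_lt(min(max(abs(fit1$scores - fit2$scores)),
                max(abs(fit1$scores + fit2$scores))), 1e-8)
})

test_that("the mfpca fit object behaves like a classed model fit", {
  set.seed(408)
  arr <- array(stats::rnorm(15 * 12 * 4), c(15, 12, 4))
  fit <- mfpca(arr, M = 4)
  expect_s3_class(fit, "mfpca")
  expect_length(scores(fit), 15L)
  expect_output(print(fit), "Multivariate FPCA")
  sm <- summary(fit)
  expect_output(print(sm), "first mode")
  # projecting the training data reproduces the training scores
  expect_equal(predict(fit, arr), fit$scores, tolerance = 1e-10)
})
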