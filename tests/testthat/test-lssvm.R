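blobs <- function(n = 10, gap = 6, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p, gap), n, p))
  list(x = x, y = rep(c(1, -1), each = n))
}

test_that("the RBF kernel has the right fixed points and limits", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 2), 1)
  z <- c(1, 2, 3 + sqrt(2))   # squared distance 2 == sigma2
  expect_equal(rbf_kernel(x, z, 2), exp(-1))
  expect_equal(rbf_kernel(x, z, 1e12), 1, tolerance = 1e-10)
  expect_error(rbf_kernel(x, z, 0), "positive")
})

test_that("the fitted coefficients satisfy the dual linear system", {
  d <- blobs(10, gap = 3, seed = 2)
  fit <- lssvm(d$x, d$y, gamma = 5, sigma2 = 2)
  expect_lt(fit$residual, 1e-8)
  expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
  # reconstruct the system independently and check the solution solves it
  K <- exp(-as.matrix(dist(fit$x))^2 / fit$sigma2)
  A <- rbind(c(0, d$y), cbind(d$y, tcrossprod(d$y) * K + diag(20) / 5))
  expect_lt(max(abs(A %*% c(fit$b, fit$alpha) - c(0, rep(1, 20)))), 1e-8)
})

test_that("well-separated blobs are classified perfectly", {
  d <- blobs(10, gap = 6, seed = 3)
  fit <- lssvm(d$x, d$y, gamma = 100, sigma2 = 1)
  expect_equal(predict(fit, d$x), d$y)
  newx <- rbind(c(0, 0), c(6, 6))
  expect_equal(predict(fit, newx), c(1, -1))
  expect_error(predict(fit, matrix(0, 1, 3)), "columns")
})

test_that("the 4-point XOR is fit exactly with a narrow kernel and large gamma", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  fit <- lssvm(x, y, gamma = 1e4, sigma2 = 0.1, standardize = FALSE)
  expect_equal(predict(fit, x), y)
  expect_lt(fit$residual, 1e-8)
})

test_that("decision values match the naive per-sample kernel-sum oracle", {
  set.seed(9)
  d <- blobs(8, gap = 2, seed = 9, p = 3)
  fit <- lssvm(d$x, d$y, gamma = 3, sigma2 = 4)
  newx <- matrix(rnorm(15), 5, 3)
  expect_equal(predict(fit, newx, type = "decision"),
               oracle_lssvm_decision(fit, newx), tolerance = 1e-10)
})

test_that("training error vanishes as gamma grows on separable data", {
  d <- blobs(15, gap = 3, seed = 5)
  errs <- sapply(c(0.01, 1, 1e4), function(g) {
    mean(predict(lssvm(d$x, d$y, gamma = g, sigma2 = 5), d$x) != d$y)
  })
  expect_true(all(diff(errs) <= 0))
  expect_equal(errs[3], 0)
})

test_that("standardisation parameters come from training data only", {
  d <- blobs(10, gap = 6, seed = 7)
  fit <- lssvm(d$x, d$y, gamma = 50, sigma2 = 2)
  expect_equal(fit$center, colMeans(d$x))
  # predictions on shifted query points use the stored parameters, so a
  # point at the healthy training mean stays healthy
  expect_equal(predict(fit, matrix(colMeans(d$x[1:10, ]), 1)), 1)
})

test_that("stratified folds balance classes and sizes", {
  y <- rep(c(1, -1), each = 100)
  folds <- watercore:::stratified_folds(y, 10, seed = 4)
  tab <- table(folds, y)
  expect_true(all(tab == 10))   # 20 per fold, both classes equally
})

test_that("tuning returns the single candidate untouched and an honest CV score", {
  d <- blobs(10, gap = 6, seed = 8)
  tuned <- tune_lssvm(d$x, d$y, gamma_grid = 7, sigma2_grid = 3,
                      n_folds = 4, seed = 2)
  expect_equal(tuned$gamma, 7)
  expect_equal(tuned$sigma2, 3)
  # recompute the CV objective independently over the same folds
  folds <- watercore:::stratified_folds(d$y, 4, seed = 2)
  correct <- 0
  for (f in 1:4) {
    fit <- lssvm(d$x[folds != f, ], d$y[folds != f], 7, 3)
    correct <- correct + sum(predict(fit, d$x[folds == f, , drop = FALSE]) ==
                               d$y[folds == f])
  }
  expect_equal(tuned$cv_accuracy, correct / 20)
})

test_that("coarse-to-fine tuning is deterministic and beats chance on blobs", {
  d <- blobs(15, gap = 5, seed = 10)
  t1 <- tune_lssvm(d$x, d$y, gamma_grid = 10^(-1:2), sigma2_grid = 10^(-1:2),
                   n_folds = 5, seed = 3)
  t2 <- tune_lssvm(d$x, d$y, gamma_grid = 10^(-1:2), sigma2_grid = 10^(-1:2),
                   n_folds = 5, seed = 3)
  expect_identical(t1, t2)
  expect_gt(t1$cv_accuracy, 0.9)
  expect_error(tune_lssvm(d$x, d$y, n_folds = 31), "folds")
})
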