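test_that("stratification bins are quantile blocks with stable ties", {
  expect_equal(stratify_bins(c(1, 2, 3, 4), 4), 1:4)
  expect_warning(b <- stratify_bins(rep(2, 10), 4), "constant")
  expect_true(all(b == 1L))

  set.seed(17)
  y <- sample(1:100)
  bins <- stratify_bins(y, 4)
  # brute-force oracle: quartile blocks of the sorted values
  for (k in 1:4) {
    expect_setequal(y[bins == k], sort(y)[(25 * (k - 1) + 1):(25 * k)])
  }

  # stable tie-breaking: equal values are assigned in order of appearance
  yt <- c(5, 5, 5, 5, 1, 1, 9, 9)
  expect_equal(stratify_bins(yt, 2), c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L))
})

test_that("folds are stratified, balanced and deterministic", {
  y <- rnorm(20, 0, 1)
  f <- make_folds(y, 10, 4, seed = 1)
  expect_true(all(table(f) == 2))

  set.seed(2)
  y <- rnorm(137)
  f1 <- make_folds(y, 10, 4, seed = 5)
  f2 <- make_folds(y, 10, 4, seed = 5)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, 10, 4, seed = 6)))
  # overall and per-bin balance within 1
  expect_lte(diff(range(table(f1))), 1)
  bins <- stratify_bins(y, 4)
  for (b in 1:4) {
    tab <- table(factor(f1[bins == b], levels = 1:10))
    expect_lte(diff(range(tab)), 1)
  }
  expect_error(make_folds(rnorm(5), 10, 4, seed = 1), "exceeds")
})

test_that("ridge at lambda 0 reduces to least squares on a toy line", {
  m <- ridge_fit(cbind(1:3), c(2, 4, 6), lambda = 0, standardize = FALSE)
  cf <- coef(m)
  expect_equal(unname(cf[1]), 0, tolerance = 1e-10)
  expect_equal(unname(cf[2]), 2, tolerance = 1e-10)
  expect_equal(predict(m, cbind(c(10, -1))), c(20, -2), tolerance = 1e-9)
})

test_that("extreme penalties shrink coefficients to the mean model", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40, 10)
  m <- ridge_fit(X, y, lambda = 1e16)
  expect_true(all(abs(m$coefficients) < 1e-10))
  expect_equal(predict(m, X), rep(mean(y), 40), tolerance = 1e-8)
})

test_that("ridge solutions match the normal-equations oracle", {
  set.seed(11)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rnorm(20)
    lam <- 10^sample(-6:6, 1)
    m <- ridge_fit(X, y, lam)
    expect_equal(m$coefficients, ridge_oracle_coef(X, y, lam),
                 tolerance = 1e-8)
  }
  expect_error(ridge_fit(matrix(c(1, NA), 2, 1), c(1, 2), 1), "non-finite")
})

test_that("coefficient norms shrink monotonically in the penalty", {
  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30) + X[, 1]
  norms <- vapply(10^seq(-4, 8, by = 1), function(l) {
    sqrt(sum(ridge_fit(X, y, l)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("penalty selection favors least shrinkage on noiseless data", {
  set.seed(13)
  X <- matrix(rnorm(120 * 4), 120, 4)
  y <- drop(X %*% c(1, -2, 0.5, 3))
  cfg <- training_config(seed = 1)
  lam <- select_penalty(X, y, cfg)
  expect_lte(as.numeric(lam), 1e-10)

  single <- training_config(penalty_grid = 42, seed = 1)
  expect_equal(as.numeric(select_penalty(X, y, single)), 42)
})

test_that("RMSE selection picks heavy shrinkage for pure-noise features", {
  hits <- vapply(1:15, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(200 * 20), 200, 20)
    y <- rnorm(200)
    cfg <- training_config(selection_metric = "rmse", seed = s)
    as.numeric(select_penalty(X, y, cfg)) >= 1
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("penalty selection is deterministic under the seed", {
  set.seed(14)
  X <- matrix(rnorm(80 * 5), 80, 5)
  y <- rnorm(80) + X[, 2]
  cfg <- training_config(seed = 3)
  expect_identical(as.numeric(select_penalty(X, y, cfg)),
                   as.numeric(select_penalty(X, y, cfg)))
})

test_that("out-of-fold prediction is complete, leak-free and deterministic", {
  d <- make_dataset(150, 0.5, seed = 21, dim = 16)
  cfg <- training_config(seed = 2)
  res <- cross_validated_predict(d$X, d$y, cfg)

  expect_length(res$y_predicted, 150)
  expect_false(anyNA(res$y_predicted))
  expect_setequal(unique(res$fold_assignment), 1:10)
  # every observation is predicted exactly once: the fold map is a partition
  expect_equal(sum(table(res$fold_assignment)), 150)
  expect_equal(res$accuracy_r, cor(res$y_observed, res$y_predicted))
  expect_true(all(res$lambda_per_fold %in% cfg$penalty_grid))

  res2 <- cross_validated_predict(d$X, d$y, cfg)
  expect_identical(res$y_predicted, res2$y_predicted)
  expect_identical(res$accuracy_p, res2$accuracy_p)
})

test_that("an exact linear encoding of the outcome is recovered", {
  set.seed(23)
  y <- rnorm(200, 20, 5)
  W <- matrix(rnorm(3 * 12), 3, 12)
  X <- cbind(y, y^2 / 40, sqrt(abs(y))) %*% W
  res <- cross_validated_predict(X, y, training_config(seed = 4))
  expect_gt(res$accuracy_r, 0.99)
  expect_lt(res$accuracy_p, 0.01)
})

test_that("degenerate outcomes are rejected with a clear error", {
  X <- matrix(rnorm(60), 30, 2)
  expect_error(cross_validated_predict(X, rep(3, 30), training_config()),
               "constant")
})

test_that("difference targets are centered differences", {
  expect_equal(difference_target(c(1, 2, 3), c(3, 2, 1)), c(-2, 0, 2))
  expect_equal(difference_target(c(4, 4), c(1, 9)), c(4, -4))
  y1 <- rnorm(50, 20); y2 <- rnorm(50, 12)
  expect_equal(mean(difference_target(y1, y2)), 0)
  expect_equal(difference_target(y1, y1), rep(0, 50))
  expect_error(difference_target(1:3, 1:4), "length")
})
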