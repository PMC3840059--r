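test_that("the hard-margin separator of two symmetric points is recovered", {
  m <- train_svm(matrix(c(-1, 1), ncol = 1), c(-1, 1), C = 1000)
  expect_equal(unname(m$w), 1, tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
})

test_that("separable data is fit with zero training error at large C", {
  g <- gaussian_cohort(10, 3, shift = 6, seed = 1)
  m <- train_svm(g$X, g$y, C = 100)
  expect_equal(mean(predict(m, g$X) == g$y), 1)
})

test_that("contradictory duplicated labels force irreducible training error", {
  X <- matrix(c(0, 0, 1), ncol = 1)
  y <- c(-1, 1, 1)
  for (C in c(0.1, 1, 100)) {
    m <- train_svm(X, y, C)
    expect_gte(mean(predict(m, X) != y), 1 / 3 - 1e-12)
  }
})

test_that("negating the labels negates the separating hyperplane", {
  g <- gaussian_cohort(8, 4, shift = 2, seed = 2)
  m1 <- train_svm(g$X, g$y, C = 10)
  m2 <- train_svm(g$X, -g$y, C = 10)
  expect_equal(m1$w, -m2$w, tolerance = 1e-6)
  expect_equal(m1$b, -m2$b, tolerance = 1e-6)
})

test_that("single-class data and invalid C are rejected", {
  X <- matrix(rnorm(10), 5)
  expect_error(train_svm(X, rep(1, 5), 1), "both classes")
  expect_error(train_svm(X, c(-1, -1, -1, 1, 1), 0), "positive")
  expect_error(train_svm(X, c(0, 1, 1, 1, -1), 1), "-1 or 1")
})

test_that("nested CV reaches high accuracy on well-separated classes", {
  g <- gaussian_cohort(12, 3, shift = 5, seed = 3)
  r <- nested_cv(g$X, g$y, repeats = 5, seed = 1)
  expect_gte(r$accuracy_mean, 0.9)
  expect_true(all(r$chosen_C %in% r$settings$C_grid))
})

test_that("nested CV sits at chance on label-independent features", {
  accs <- vapply(1:8, function(i) {
    g <- gaussian_cohort(12, 5, shift = 0, seed = 10 + i)
    nested_cv(g$X, g$y, repeats = 2, seed = i)$accuracy_mean
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-12)
})

test_that("nested CV reports are reproducible and column-order invariant", {
  g <- gaussian_cohort(8, 4, shift = 1.5, seed = 4)
  r1 <- nested_cv(g$X, g$y, repeats = 4, seed = 9)
  r2 <- nested_cv(g$X, g$y, repeats = 4, seed = 9)
  expect_identical(r1, r2)
  r3 <- nested_cv(g$X[, c(3, 1, 4, 2)], g$y, repeats = 4, seed = 9)
  expect_equal(r1$per_repeat, r3$per_repeat, tolerance = 1e-9)
})

test_that("duplicating every sample leaves the accuracy estimate unchanged within SE", {
  ## checked in the separated regime: near the decision boundary CV with
  ## exact duplicates is optimistic (a copy of each held-out point sits in
  ## the training half), which is a property of cross-validation, not a bug
  g <- gaussian_cohort(10, 3, shift = 3, seed = 5)
  r1 <- nested_cv(g$X, g$y, repeats = 10, seed = 1)
  r2 <- nested_cv(rbind(g$X, g$X), c(g$y, g$y), repeats = 10, seed = 1)
  tol <- 3 * sqrt(r1$accuracy_se^2 + r2$accuracy_se^2)
  expect_lt(abs(r1$accuracy_mean - r2$accuracy_mean), max(tol, 0.05))
})

test_that("stratification requirements are enforced", {
  X <- matrix(rnorm(8), 4)
  expect_error(nested_cv(X, c(-1, 1, 1, 1), repeats = 2), "at least 2 members")
  expect_error(nested_cv(X[1:3, ], c(-1, 1, 1), repeats = 2), "at least 4")
})

test_that("permutation p-values use the add-one rule and are never zero", {
  g <- gaussian_cohort(6, 2, shift = 8, seed = 6)   # effectively perfect separation
  pt <- permutation_test(g$X, g$y, n_perm = 19, seed = 3, repeats = 2)
  expect_gt(pt$p_value, 0)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_errors <= pt$observed$error_mean + 1e-12)) / 20)
  ## strongly separated data should beat nearly every permutation
  expect_lte(pt$p_value, 0.1)
  ## reproducibility
  pt2 <- permutation_test(g$X, g$y, n_perm = 19, seed = 3, repeats = 2)
  expect_identical(pt, pt2)
})

test_that("feature-subset evaluation matches restriction by hand", {
  g <- gaussian_cohort(8, 5, shift = 3, seed = 7)
  r_all <- evaluate_feature_set(g$X, g$y, seq_len(5), repeats = 3, seed = 2)
  r_full <- nested_cv(g$X, g$y, repeats = 3, seed = 2)
  expect_equal(r_all$per_repeat, r_full$per_repeat)
  expect_error(evaluate_feature_set(g$X, g$y, integer(0)), "nonempty")
  ## a single perfectly separating feature suffices
  X <- cbind(sep = rep(c(-2, 2), each = 10), matrix(rnorm(40), 20))
  y <- rep(c(-1, 1), each = 10)
  r1 <- evaluate_feature_set(X, y, 1, repeats = 5, seed = 1)
  expect_gte(r1$accuracy_mean, 0.95)
})
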