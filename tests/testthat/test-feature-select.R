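test_that("B4 maps a component to its largest absolute loading", {
  expect_equal(b4_map(c(0.1, -0.9, 0.3)), 2)
  expect_equal(b4_map(c(0.5, 0.5)), 1)          # tie -> lowest index
  expect_equal(b4_map(c(0, 0, 1, 0)), 3)
  expect_error(b4_map(c(0, 0)), "all zero")
})

test_that("group standard scores match hand computation and symmetry", {
  X <- matrix(c(0, 0, 2, 2), ncol = 1)
  y <- c(-1, -1, 1, 1)
  z <- group_standard_scores(X, y)
  expect_equal(unname(z["1", 1]), sqrt(3) / 2, tolerance = 1e-10)    # +0.866
  expect_equal(unname(z["-1", 1]), -sqrt(3) / 2, tolerance = 1e-10)
  ## balanced classes: means sum to zero per feature
  set.seed(1)
  Xb <- matrix(rnorm(40), 8, 5)
  yb <- rep(c(-1, 1), 4)
  zb <- group_standard_scores(Xb, yb)
  expect_lt(max(abs(colSums(zb))), 1e-8)
  ## constant features score zero for both groups
  zc <- group_standard_scores(cbind(Xb, const = 7), yb)
  expect_equal(unname(zc[, "const"]), c(0, 0))
  ## invariance to affine rescaling of a column
  Xa <- Xb; Xa[, 2] <- 5 * Xa[, 2] - 11
  expect_equal(group_standard_scores(Xa, yb), group_standard_scores(Xb, yb),
               tolerance = 1e-10)
})

test_that("RFE eliminates constant features first and keeps a planted separator", {
  set.seed(2)
  X <- cbind(matrix(rnorm(20 * 8), 20, 8),
             const = 0,
             sep = rep(c(-3, 3), each = 10))
  y <- rep(c(-1, 1), each = 10)
  r <- rfe_rank(X, y, C = 50, n_keep = 3)
  expect_equal(r$elimination_trace[1], 9)          # the zero-variance column
  expect_true(10 %in% r$selected)                  # the separating column survives
  expect_setequal(r$ordering, 1:10)                # a permutation of all features
  expect_error(rfe_rank(X, y, n_keep = 10), "smaller")
})

test_that("a planted separator survives RFE across seeds", {
  hits <- vapply(1:10, function(i) {
    set.seed(100 + i)
    X <- cbind(matrix(rnorm(24 * 20), 24, 20),
               sep = rep(c(-2.5, 2.5), each = 12) + rnorm(24, sd = 0.3))
    y <- rep(c(-1, 1), each = 12)
    21 %in% rfe_rank(X, y, C = 50, n_keep = 5)$selected
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("duplicated informative features are resolved deterministically", {
  set.seed(3)
  sep <- rep(c(-3, 3), each = 10) + rnorm(20, sd = 0.2)
  X <- cbind(a = sep, b = sep, matrix(rnorm(20 * 4), 20, 4))
  y <- rep(c(-1, 1), each = 10)
  r1 <- rfe_rank(X, y, C = 50, n_keep = 2)
  r2 <- rfe_rank(X, y, C = 50, n_keep = 2)
  expect_identical(r1, r2)
  expect_true(any(c(1, 2) %in% r1$selected))       # at least one copy survives
})

test_that("RFE in PC space reduces to raw RFE for identity loadings", {
  set.seed(4)
  g <- gaussian_cohort(10, 6, shift = 2, seed = 4)
  model <- fit_pca(g$X)
  ## synthetic identity model: PCs are the features themselves
  ident <- model
  ident$eigenvectors <- diag(6)
  ident$column_means <- rep(0, 6)
  scores <- g$X
  r_pca <- rfe_pca_rank(scores, g$y, ident, C = 10, n_keep = 2)
  r_raw <- rfe_rank(g$X, g$y, C = 10, n_keep = 2)
  expect_equal(r_pca$mapped_features, r_raw$selected)
})

test_that("top-PC selection maps the dominant variance direction to its feature", {
  set.seed(5)
  t_ <- rnorm(30, sd = 4)
  X <- cbind(0.2 * rnorm(30), t_ + 0.1 * rnorm(30), 0.2 * rnorm(30))
  m <- fit_pca(X)
  sel <- top_pca_select(m, 1)
  expect_equal(sel$mapped_features, 2)             # variance lives in column 2
  expect_equal(top_pca_select(m, 3)$selected_pcs, 1:3)
  expect_error(top_pca_select(m, 4), "between 1 and")
})

test_that("planted discriminative subgraph classes are recovered by RFE on censuses", {
  cat5 <- build_catalog(5)
  planted <- planted_class_keys(5)
  hits <- vapply(1:5, function(i) {
    coh <- generate_cohort(n_per_class = 10, n_nodes = 80, effect_size = 8,
                           seed = 500 + i)
    X <- embed_cohort(coh$networks, cat5)
    r <- rfe_rank(X, coh$labels, C = 50, n_keep = 10)
    mean(planted %in% cat5$classes$key[r$selected])
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})
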