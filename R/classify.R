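#' Train a linear soft-margin SVM
#'
#' Minimizes the usual hinge-loss objective `|w|^2/2 + C sum(xi_i)` with a
#' linear kernel, delegating the convex problem to the LIBSVM solver
#' (package e1071).  Features are used as-is (no internal standardization):
#' PC scores are already variance-ordered, and raw counts can be
#' standardized upstream if desired.
#'
#' For numerical conditioning the training matrix is divided by one global
#' factor (the pooled standard deviation of all its entries) before the
#' solver runs; `C` is defined relative to these conditioned features.
#' Because the factor is shared by all columns, relative feature geometry
#' and the `w^2` ranking used by feature elimination are unaffected, and
#' the returned `w`, `b` are expressed on the original feature scale.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Labels in `{-1, 1}`; both classes must be present.
#' @param C Positive cost parameter.
#' @return An object of class `svm_model` with `w` (weight vector), `b`
#'   (bias), `C`, and the underlying e1071 fit.  The decision value of a
#'   sample x is `w . x + b`; its sign (ties to +1) is the predicted class.
#' @export
train_svm <- function(X, y, C) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or 1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (!is.numeric(C) || length(C) != 1 || C <= 0) stop("C must be a positive number")
  s <- global_scale(X)
  Xs <- X / s
  fit <- e1071::svm(Xs, factor(y, levels = c(-1, 1)), type = "C-classification",
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV) / s
  b <- -fit$rho
  ## LIBSVM orients the decision function toward the class of the first
  ## training sample; flip so that positive decision values mean class +1.
  f <- drop(X %*% w + b)
  pred <- as.numeric(as.character(predict(fit, Xs)))
  agree <- sum(sign(f) * pred > 0)
  disagree <- sum(sign(f) * pred < 0)
  if (disagree > agree) { w <- -w; b <- -b }
  structure(list(w = w, b = b, C = C, fit = fit), class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  f <- drop(as.matrix(newdata) %*% object$w + object$b)
  ifelse(f >= 0, 1, -1)
}

#' Decision values of a linear SVM
#'
#' @param model A [train_svm()] model.
#' @param X Feature matrix.
#' @return Numeric vector `w . x + b`.
#' @export
svm_decision <- function(model, X) {
  drop(as.matrix(X) %*% model$w + model$b)
}

## Single conditioning factor shared by every SVM entry point: the pooled
## standard deviation of all matrix entries (1 for a constant matrix).
global_scale <- function(X) {
  s <- stats::sd(as.numeric(X))
  if (!is.finite(s) || s == 0) 1 else s
}

## Leave-one-out accuracy for one C on a training set, via LIBSVM's
## internal cross-validation (fold count = sample count, so the partition
## is the deterministic leave-one-out one).
loo_accuracy <- function(X, y, C) {
  fit <- e1071::svm(X / global_scale(X), factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "linear", cost = C,
                    scale = FALSE, cross = nrow(X))
  fit$tot.accuracy / 100
}

## Stratified 2-fold split: each class is shuffled and dealt half/half.
stratified_two_fold <- function(y) {
  fold <- integer(length(y))
  for (cls in c(-1, 1)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    h <- ceiling(length(idx) / 2)
    fold[idx[seq_len(h)]] <- 1L
    fold[idx[-seq_len(h)]] <- 2L
  }
  fold
}

#' Nested cross-validation of a linear SVM
#'
#' Outer loop: repeated stratified 2-fold splits estimating the
#' generalization error.  Inner loop: on each outer training half,
#' leave-one-out cross-validation over the `C_grid` chooses the cost
#' parameter (ties go to the smallest C, i.e. the stronger
#' regularization).  The chosen-C model is refit on the training half and
#' scored on the held-out half; fold accuracies are averaged per repeat, and
#' the mean and standard error are taken across repeats.
#'
#' @param X Feature matrix (N x p).
#' @param y Labels in `{-1, 1}`; each class needs at least 2 members.
#' @param C_grid Candidate cost values.
#' @param repeats Number of random outer splits (default 50).
#' @param seed RNG seed controlling the outer splits.
#' @return An object of class `classification_report`: `accuracy_mean`,
#'   `accuracy_se` (across repeats; `NA` for a single repeat),
#'   `error_mean`, per-repeat and per-fold accuracies, chosen C per outer
#'   fold, and the settings used.
#' @export
nested_cv <- function(X, y, C_grid = c(0.01, 0.1, 1, 10, 50, 100),
                      repeats = 50, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or 1")
  if (length(y) != nrow(X)) stop("labels must match the rows of X")
  if (length(y) < 4) stop("nested CV needs at least 4 samples")
  if (min(table(y)) < 2) stop("each class needs at least 2 members for stratified folds")
  if (length(C_grid) == 0) stop("C_grid must be nonempty")
  C_grid <- sort(as.numeric(C_grid))

  acc_fold <- matrix(NA_real_, nrow = repeats, ncol = 2)
  chosen_C <- matrix(NA_real_, nrow = repeats, ncol = 2)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_two_fold(y)
      for (k in 1:2) {
        tr <- fold != k
        inner <- vapply(C_grid, function(C) loo_accuracy(X[tr, , drop = FALSE], y[tr], C),
                        numeric(1))
        Cbest <- C_grid[which.max(inner)]   # first max = smallest C on ties
        m <- train_svm(X[tr, , drop = FALSE], y[tr], Cbest)
        pred <- predict(m, X[!tr, , drop = FALSE])
        acc_fold[r, k] <- mean(pred == y[!tr])
        chosen_C[r, k] <- Cbest
      }
    }
  })
  per_repeat <- rowMeans(acc_fold)
  structure(list(
    accuracy_mean = mean(per_repeat),
    accuracy_se = if (repeats > 1) stats::sd(per_repeat) / sqrt(repeats) else NA_real_,
    error_mean = 1 - mean(per_repeat),
    per_repeat = per_repeat,
    per_fold = acc_fold,
    chosen_C = chosen_C,
    settings = list(C_grid = C_grid, repeats = repeats, seed = seed,
                    n = length(y), p = ncol(X))
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("nested-CV accuracy: %.3f +/- %.3f (error %.3f; %d repeats of stratified 2-fold)\n",
              x$accuracy_mean, x$accuracy_se, x$error_mean, x$settings$repeats))
  invisible(x)
}

#' Permutation test of classification error
#'
#' Reruns the full nested cross-validation on label-permuted copies of the
#' data to build an empirical null distribution of test errors.  The
#' p-value uses the add-one convention
#' `p = (1 + #{null error <= observed error}) / (n_perm + 1)`, a left-tail
#' test of low error that can never return 0.
#'
#' @param X Feature matrix.
#' @param y Labels in `{-1, 1}`.
#' @param n_perm Number of label permutations (the connectome study used
#'   1000).
#' @param seed RNG seed; permutation b runs with its own derived seed.
#' @param C_grid,repeats Passed to [nested_cv()] for both the observed and
#'   every null run.
#' @return List with `p_value`, `observed` (the observed
#'   `classification_report`), `null_errors`, `n_perm`, `seed`.
#' @export
permutation_test <- function(X, y, n_perm = 1000, seed = 1,
                             C_grid = c(0.01, 0.1, 1, 10, 50, 100), repeats = 5) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  obs <- nested_cv(X, y, C_grid = C_grid, repeats = repeats, seed = seed)
  seeds <- child_seeds(seed, n_perm + 1)
  perms <- with_seed(seeds[n_perm + 1],
                     replicate(n_perm, sample(y), simplify = FALSE))
  null_errors <- vapply(seq_len(n_perm), function(b) {
    nested_cv(X, perms[[b]], C_grid = C_grid, repeats = repeats,
              seed = seeds[b])$error_mean
  }, numeric(1))
  p <- (1 + sum(null_errors <= obs$error_mean + 1e-12)) / (n_perm + 1)
  list(p_value = p, observed = obs, null_errors = null_errors,
       n_perm = n_perm, seed = seed)
}

#' Nested cross-validation on a feature subset
#'
#' Restricts the cohort to the given feature columns and reruns
#' [nested_cv()]; used to re-evaluate the top subgraphs chosen by a feature
#' selection method.
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param features Nonempty integer or character vector of columns.
#' @param ... Passed to [nested_cv()].
#' @return A `classification_report`.
#' @export
evaluate_feature_set <- function(X, y, features, ...) {
  if (length(features) == 0) stop("feature subset must be nonempty")
  nested_cv(as.matrix(X)[, features, drop = FALSE], y, ...)
}
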