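#' SVM-based recursive feature elimination
#'
#' Iteratively trains a linear SVM at fixed cost `C`, scores every remaining
#' feature by `w_i^2` (the change in the margin cost caused by dropping
#' feature i, for a linear model), and removes the lowest-scoring `step`
#' features until `n_keep` remain.  Score ties are broken by removing the
#' higher-index feature first, so lower indices survive longer and the
#' procedure is deterministic.
#'
#' @param X Feature matrix (at least 2 columns).
#' @param y Labels in `{-1, 1}`.
#' @param C Cost parameter used during elimination (default 50).
#' @param step Features removed per iteration (default 1).
#' @param n_keep Size of the surviving feature set (must be `< ncol(X)`).
#' @return An object of class `feature_ranking`: `ordering` (all feature
#'   indices, most to least discriminative), `selected` (the `n_keep`
#'   survivors, ranked), `elimination_trace` (indices in removal order),
#'   `method = "RFE-raw"`.
#' @export
rfe_rank <- function(X, y, C = 50, step = 1, n_keep = 10) {
  X <- as.matrix(X)
  M <- ncol(X)
  if (M < 2) stop("RFE needs at least 2 features")
  if (n_keep >= M) stop("n_keep must be smaller than the number of features")
  if (n_keep < 1) stop("n_keep must be at least 1")
  remaining <- seq_len(M)
  trace <- integer(0)
  while (length(remaining) > n_keep) {
    m <- train_svm(X[, remaining, drop = FALSE], y, C)
    score <- m$w^2
    k <- min(step, length(remaining) - n_keep)
    ## remove k smallest scores; on ties drop the higher original index first
    ord <- order(score, -remaining)
    drop_idx <- ord[seq_len(k)]
    trace <- c(trace, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  m <- train_svm(X[, remaining, drop = FALSE], y, C)
  surv_order <- remaining[order(-m$w^2, remaining)]
  ordering <- c(surv_order, rev(trace))
  nm <- colnames(X)
  structure(list(ordering = ordering,
                 selected = surv_order,
                 elimination_trace = trace,
                 feature_names = if (!is.null(nm)) nm[ordering] else NULL,
                 method = "RFE-raw", C = C, step = step, n_keep = n_keep),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking (%s): %d features, top %d kept\n",
              x$method, length(x$ordering), length(x$selected)))
  invisible(x)
}

#' Map a principal component to its dominant feature (B4 rule)
#'
#' Returns the index of the original feature with the largest absolute
#' loading on the component; ties resolve to the lowest index.
#'
#' @param loading Nonzero numeric loading vector (one PC column).
#' @return Feature index.
#' @export
b4_map <- function(loading) {
  loading <- as.numeric(loading)
  if (all(loading == 0)) stop("loading vector is all zero")
  which.max(abs(loading))
}

#' Recursive feature elimination in PC space with B4 mapping
#'
#' Runs [rfe_rank()] on the PC score matrix and maps each surviving
#' component back to one original subgraph feature via [b4_map()] on its
#' loading vector.  Duplicate hits (two PCs dominated by the same feature)
#' are reported as-is.
#'
#' @param scores PC score matrix (subjects x components), as produced by
#'   [pca_project()].
#' @param y Labels.
#' @param model The [fit_pca()] model that produced `scores`.
#' @param C,step,n_keep As in [rfe_rank()].
#' @return A `feature_ranking` with `method = "RFE-pca"`, plus
#'   `selected_pcs` and `mapped_features` (multiset of original feature
#'   indices).
#' @export
rfe_pca_rank <- function(scores, y, model, C = 50, step = 1, n_keep = 10) {
  stopifnot(inherits(model, "pca_model"))
  r <- rfe_rank(scores, y, C = C, step = step, n_keep = n_keep)
  mapped <- vapply(r$selected, function(pc) b4_map(model$eigenvectors[, pc]), integer(1))
  nm <- rownames(model$eigenvectors)
  r$method <- "RFE-pca"
  r$selected_pcs <- r$selected
  r$mapped_features <- mapped
  r$mapped_names <- if (!is.null(nm)) nm[mapped] else NULL
  r
}

#' Top-eigenvalue PC selection with B4 mapping
#'
#' Selects the k components with the largest eigenvalues and maps each to
#' its dominant original feature.
#'
#' @param model A [fit_pca()] model.
#' @param k Number of components, `1 <= k <= M`.
#' @return List with `selected_pcs`, `mapped_features`, `mapped_names`,
#'   `method = "topPCA"`.
#' @export
top_pca_select <- function(model, k) {
  stopifnot(inherits(model, "pca_model"))
  M <- ncol(model$eigenvectors)
  if (k < 1 || k > M) stop("k must be between 1 and ", M)
  pcs <- seq_len(k)
  mapped <- vapply(pcs, function(pc) b4_map(model$eigenvectors[, pc]), integer(1))
  nm <- rownames(model$eigenvectors)
  list(selected_pcs = pcs, mapped_features = mapped,
       mapped_names = if (!is.null(nm)) nm[mapped] else NULL,
       method = "topPCA")
}

#' Per-class mean standard scores
#'
#' Each feature is z-scored across the pooled cohort (pooled mean, pooled
#' n-1 standard deviation); the z-scores are then averaged within each
#' class.  For balanced classes the two class means of any feature are
#' symmetric about zero.  Constant features get z = 0.
#'
#' @param X Feature matrix.
#' @param y Labels in `{-1, 1}`.
#' @return An object of class `group_standard_scores`: matrix with rows
#'   `"-1"` and `"1"` and one column per feature.
#' @export
group_standard_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2) stop("at least 2 subjects are required")
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  Z <- sweep(X, 2, mu)
  ok <- s > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, s[ok], "/")
  Z[, !ok] <- 0
  out <- rbind(`-1` = colMeans(Z[y == -1, , drop = FALSE]),
               `1` = colMeans(Z[y == 1, , drop = FALSE]))
  colnames(out) <- colnames(X)
  structure(out, class = c("group_standard_scores", class(out)))
}
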