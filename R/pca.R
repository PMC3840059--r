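#' Principal components analysis of an embedding matrix
#'
#' Zero-means each column, forms the covariance matrix (1/(N-1)
#' normalization) and eigendecomposes it.  Eigenvectors are sorted by
#' decreasing eigenvalue and their sign is fixed deterministically: the
#' largest-magnitude loading of each component is made positive (first such
#' entry on ties).  Tiny negative eigenvalues from finite arithmetic are
#' clipped to zero.
#'
#' @param X Numeric matrix, rows = subjects (N >= 2), columns = features.
#' @return An object of class `pca_model`: `column_means`, `eigenvalues`
#'   (nonincreasing), `eigenvectors` (orthonormal columns),
#'   `n_components_suggested` (scree heuristic, see [scree_cutoff()]).
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA requires at least 2 rows")
  cm <- colMeans(X)
  Z <- sweep(X, 2, cm)
  C <- crossprod(Z) / (nrow(X) - 1)
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  U <- ee$vectors
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  rownames(U) <- colnames(X)
  structure(list(column_means = cm,
                 eigenvalues = vals,
                 eigenvectors = U,
                 n_components_suggested = scree_cutoff(vals)),
            class = "pca_model")
}

#' Project data onto the first p principal components
#'
#' Computes `Y = Z U_p` where `Z` centers the new data with the model's
#' stored column means and `U_p` holds the first `p` eigenvectors.
#'
#' @param model A [fit_pca()] model.
#' @param X Data matrix with the same columns as the training data.
#' @param p Number of components, `1 <= p <= M`.
#' @return N x p score matrix.
#' @export
pca_project <- function(model, X, p) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  M <- ncol(model$eigenvectors)
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p > M)
    stop("p must be between 1 and the number of components (", M, ")")
  if (ncol(X) != length(model$column_means))
    stop("X has the wrong number of columns for this model")
  Z <- sweep(X, 2, model$column_means)
  Y <- Z %*% model$eigenvectors[, seq_len(p), drop = FALSE]
  colnames(Y) <- paste0("PC", seq_len(p))
  Y
}

#' Scree heuristic: largest eigenvalue drop
#'
#' Suggests a dimensionality cutoff as the index k maximizing the
#' consecutive ratio `lambda_k / lambda_{k+1}` (over k with
#' `lambda_{k+1} > 0`); ties resolve to the smallest k.  With fewer than two
#' positive eigenvalues the suggestion is 1.  This is a reported suggestion
#' only -- classification takes the component count explicitly.
#'
#' @param eigenvalues Nonincreasing numeric vector.
#' @return Integer cutoff suggestion.
#' @export
scree_cutoff <- function(eigenvalues) {
  v <- as.numeric(eigenvalues)
  if (is.unsorted(rev(v))) stop("eigenvalues must be sorted nonincreasing")
  tol <- max(v, 0) * 1e-12
  usable <- which(v[-1] > tol)     # k with lambda_{k+1} > 0
  if (length(usable) == 0 || sum(v > tol) < 2) return(1L)
  ratios <- v[usable] / v[usable + 1]
  usable[which.max(ratios)]
}

#' Serialize / restore a PCA model as JSON
#'
#' Stores column means, eigenvalues and eigenvectors at full precision so a
#' fitted embedding basis can be reused across sessions.
#'
#' @param model A [fit_pca()] model.
#' @param path File path.
#' @return `read_pca_model` returns a `pca_model`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  jsonlite::write_json(list(
    column_means = model$column_means,
    eigenvalues = model$eigenvalues,
    eigenvectors = model$eigenvectors,
    feature_names = rownames(model$eigenvectors)
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  U <- as.matrix(obj$eigenvectors)
  if (!is.null(obj$feature_names)) rownames(U) <- obj$feature_names
  cm <- obj$column_means
  if (!is.null(obj$feature_names)) names(cm) <- obj$feature_names
  structure(list(column_means = cm,
                 eigenvalues = as.numeric(obj$eigenvalues),
                 eigenvectors = U,
                 n_components_suggested = scree_cutoff(as.numeric(obj$eigenvalues))),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  pos <- sum(x$eigenvalues > max(x$eigenvalues, 0) * 1e-12)
  cat(sprintf("pca_model: %d features, %d positive eigenvalues, scree suggestion p = %d\n",
              ncol(x$eigenvectors), pos, x$n_components_suggested))
  invisible(x)
}
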