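#' Run the full census-classification pipeline on a cohort
#'
#' Executes the whole workflow on a labeled two-class cohort: binarization
#' (for weighted inputs), the classical metric panel, the subgraph walk
#' census, PCA of the embedding, a nested-CV accuracy curve over the number
#' of principal components, an optional label-permutation test at the best
#' component count, and discriminative feature extraction with per-class
#' standard scores plus re-evaluation of the selected subset.
#'
#' Every stochastic stage consumes a seed derived from `seed`, and the
#' returned report carries all settings, so a rerun with the same inputs
#' reproduces the report exactly.
#'
#' @param networks List of [binary_network()] or [weighted_network()]
#'   objects (all the same kind).
#' @param labels Named or plain vector of class labels in `{-1, 1}`,
#'   aligned with `networks`.
#' @param walk_length Census walk length (default 8; the 149-class space).
#' @param tau Binarization threshold applied to weighted inputs (default 0).
#' @param p_grid Principal-component counts to score (default
#'   `1:min(N-1, 25, M)`).
#' @param C_grid SVM cost grid for the inner CV loop.
#' @param repeats Outer-split repeats for [nested_cv()].
#' @param n_perm Label permutations for the significance test (0 skips it).
#' @param fs_method Feature-selection method: `"RFE-raw"`, `"RFE-pca"` or
#'   `"topPCA"`.
#' @param n_keep Features (or PCs) retained by the selection method.
#' @param census_method Passed to [census_walk_counts()].
#' @param catalog Optional prebuilt [build_catalog()] (rebuilt otherwise).
#' @param seed Master seed.
#' @param outdir Optional directory; when given, the report (JSON), metric
#'   and embedding tables (CSV) and catalog (JSON) are written there.
#' @return A list report with elements `metrics`, `catalog_size`,
#'   `embedding`, `pca` (eigenvalues + scree suggestion), `accuracy_curve`,
#'   `best_p`, `classification`, `permutation`, `features`, and `settings`.
#' @export
run_pipeline <- function(networks, labels,
                         walk_length = 8, tau = 0,
                         p_grid = NULL,
                         C_grid = c(0.01, 0.1, 1, 10, 50, 100),
                         repeats = 50, n_perm = 0,
                         fs_method = c("RFE-raw", "RFE-pca", "topPCA"),
                         n_keep = 10,
                         census_method = c("factorized", "direct"),
                         catalog = NULL, seed = 1, outdir = NULL) {
  fs_method <- match.arg(fs_method)
  census_method <- match.arg(census_method)
  labels <- check_labels(labels, networks)
  ids <- names(labels)

  nets <- lapply(networks, function(nw) {
    if (inherits(nw, "weighted_network")) binarize(nw, tau) else nw
  })
  names(nets) <- ids

  metrics <- metrics_table(nets, ids = ids)
  metrics$class <- unname(labels)

  if (is.null(catalog)) catalog <- build_catalog(walk_length)
  if (catalog$walk_length != walk_length)
    stop("catalog walk length does not match walk_length")
  X <- embed_cohort(nets, catalog, method = census_method, ids = ids)

  model <- fit_pca(X)
  N <- nrow(X); M <- ncol(X)
  if (is.null(p_grid)) p_grid <- seq_len(min(N - 1, 25, M))

  seeds <- child_seeds(seed, 3)
  curve <- lapply(p_grid, function(p) {
    rep_p <- nested_cv(pca_project(model, X, p), labels, C_grid = C_grid,
                       repeats = repeats, seed = seeds[1])
    data.frame(p = p, accuracy = rep_p$accuracy_mean, se = rep_p$accuracy_se)
  })
  curve <- do.call(rbind, curve)
  best_p <- curve$p[which.max(curve$accuracy)]
  scores_best <- pca_project(model, X, best_p)
  classification <- nested_cv(scores_best, labels, C_grid = C_grid,
                              repeats = repeats, seed = seeds[1])

  permutation <- NULL
  if (n_perm > 0) {
    permutation <- permutation_test(scores_best, labels, n_perm = n_perm,
                                    seed = seeds[2], C_grid = C_grid,
                                    repeats = repeats)
  }

  features <- extract_features(X, labels, model, fs_method, n_keep,
                               C_grid = C_grid, repeats = repeats,
                               seed = seeds[3])

  report <- list(
    metrics = metrics,
    catalog_size = nrow(catalog$classes),
    embedding = X,
    pca = list(eigenvalues = model$eigenvalues,
               scree_suggestion = model$n_components_suggested),
    accuracy_curve = curve,
    best_p = best_p,
    classification = unclass_report(classification),
    permutation = if (!is.null(permutation))
      list(p_value = permutation$p_value,
           null_errors = permutation$null_errors,
           observed_error = permutation$observed$error_mean),
    features = features,
    settings = list(walk_length = walk_length, tau = tau,
                    p_grid = p_grid, C_grid = C_grid, repeats = repeats,
                    n_perm = n_perm, fs_method = fs_method, n_keep = n_keep,
                    census_method = census_method, seed = seed,
                    n_subjects = N, n_classes_in_catalog = M)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)
    write_embedding(X, file.path(outdir, "embedding.csv"))
    write_catalog(catalog, file.path(outdir, "catalog.json"))
    write_report(report, file.path(outdir, "report.json"))
  }
  report
}

check_labels <- function(labels, networks) {
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded -1 / 1")
  if (length(y) != length(networks)) stop("one label per network is required")
  nm <- names(labels)
  if (is.null(nm)) nm <- names(networks)
  if (is.null(nm)) nm <- sprintf("s%02d", seq_along(y))
  if (!is.null(names(networks)) && !is.null(names(labels))) {
    if (!setequal(names(networks), names(labels)))
      stop("label ids do not match network ids")
    y <- as.numeric(labels[names(networks)])
    nm <- names(networks)
  }
  stats::setNames(y, nm)
}

unclass_report <- function(r) {
  list(accuracy_mean = r$accuracy_mean, accuracy_se = r$accuracy_se,
       error_mean = r$error_mean, per_repeat = r$per_repeat,
       chosen_C = r$chosen_C, settings = r$settings)
}

extract_features <- function(X, labels, model, fs_method, n_keep, C_grid,
                             repeats, seed) {
  M <- ncol(X)
  if (n_keep >= M) stop("n_keep must be smaller than the number of subgraph classes")
  if (fs_method == "RFE-raw") {
    rk <- rfe_rank(X, labels, C = 50, n_keep = n_keep)
    sel <- rk$selected
  } else if (fs_method == "RFE-pca") {
    scores <- pca_project(model, X, min(nrow(X) - 1, M))
    rk <- rfe_pca_rank(scores, labels, model, C = 50,
                       n_keep = min(n_keep, ncol(scores) - 1))
    sel <- unique(rk$mapped_features)
  } else {
    rk <- top_pca_select(model, min(n_keep, M))
    sel <- unique(rk$mapped_features)
  }
  zs <- group_standard_scores(X, labels)
  subset_report <- evaluate_feature_set(X, labels, sel, C_grid = C_grid,
                                        repeats = repeats, seed = seed)
  list(method = fs_method,
       selected = sel,
       selected_keys = colnames(X)[sel],
       standard_scores = zs[, sel, drop = FALSE],
       subset_classification = unclass_report(subset_report))
}

#' Threshold-sweep robustness analysis
#'
#' Rebinarizes a weighted cohort at each threshold of a grid and recomputes
#' the cohort-mean metric panel and the nested-CV accuracy (optionally with
#' a permutation p-value) at every threshold, exposing how stable the
#' classification is to the binarization choice.  Thresholds that leave any
#' network edgeless are flagged and reported with `NA` results rather than
#' failing the sweep.
#'
#' @param weighted_networks List of [weighted_network()] objects.
#' @param labels Labels in `{-1, 1}`.
#' @param tau_grid Strictly increasing thresholds; by default 25
#'   log-spaced values spanning a 50-fold range starting at the smallest
#'   positive weight (so the lowest value keeps every edge present at
#'   `tau = 0` weights above it).
#' @param walk_length,C_grid,repeats,n_perm,p,seed,catalog As in
#'   [run_pipeline()]; `p` is the number of principal components used for
#'   classification at every threshold (default 3).
#' @return A data frame, one row per threshold: mean metric panel,
#'   accuracy, SE and (when `n_perm > 0`) permutation p-value.
#' @export
threshold_sweep <- function(weighted_networks, labels, tau_grid = NULL,
                            walk_length = 8, p = 3,
                            C_grid = c(0.01, 0.1, 1, 10, 50, 100),
                            repeats = 50, n_perm = 0, seed = 1,
                            catalog = NULL) {
  stopifnot(all(vapply(weighted_networks, inherits, logical(1), "weighted_network")))
  labels <- check_labels(labels, weighted_networks)
  if (is.null(tau_grid)) {
    wpos <- unlist(lapply(weighted_networks, function(nw) nw$W[nw$W > 0]))
    lo <- min(wpos)
    tau_grid <- c(0, exp(seq(log(lo), log(50 * lo), length.out = 24)))
  }
  if (is.unsorted(tau_grid, strictly = TRUE)) stop("tau_grid must be strictly increasing")
  if (is.null(catalog)) catalog <- build_catalog(walk_length)
  seeds <- child_seeds(seed, 2)

  rows <- lapply(tau_grid, function(tau) {
    nets <- lapply(weighted_networks, binarize, tau = tau)
    edgeless <- any(vapply(nets, function(nw) sum(nw$A) == 0, logical(1)))
    base <- data.frame(tau = tau, edgeless = edgeless)
    if (edgeless) {
      return(cbind(base, mean_degree = NA, mean_clustering = NA,
                   mean_geodesic = NA, transitivity = NA,
                   accuracy = NA, se = NA, p_value = NA))
    }
    mt <- metrics_table(nets)
    X <- embed_cohort(nets, catalog, ids = names(labels))
    model <- fit_pca(X)
    pp <- min(p, ncol(model$eigenvectors), nrow(X) - 1)
    scores <- pca_project(model, X, pp)
    rep_t <- nested_cv(scores, labels, C_grid = C_grid, repeats = repeats,
                       seed = seeds[1])
    pv <- if (n_perm > 0)
      permutation_test(scores, labels, n_perm = n_perm, seed = seeds[2],
                       C_grid = C_grid, repeats = repeats)$p_value else NA
    cbind(base, mean_degree = mean(mt$mean_degree),
          mean_clustering = mean(mt$mean_clustering),
          mean_geodesic = mean(mt$mean_geodesic),
          transitivity = mean(mt$transitivity),
          accuracy = rep_t$accuracy_mean, se = rep_t$accuracy_se,
          p_value = pv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
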