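## Synthetic cohorts: two classes of connected 100-node networks matched in
## density but differing in planted subgraph composition.  Class +1
## ("normal-like") receives modules of overlapping triangles sharing a
## common edge; class -1 ("abnormal-like") receives hub modules with
## pendant chains and a non-overlapping 4-cycle.  Both module types add the
## same number of edges, so class differences are topological rather than
## density-driven.

EDGES_PER_MODULE <- 7L

## connected Erdos-Renyi-like base graph: G(n, m) plus a repair pass that
## joins components with random bridging edges
connected_gnm <- function(n, m) {
  g <- igraph::sample_gnm(n, min(m, n * (n - 1) / 2))
  comp <- igraph::components(g)
  pick1 <- function(x) x[sample.int(length(x), 1)]   # safe for length-1 x
  while (comp$no > 1) {
    pick <- sample.int(comp$no, 2)
    a <- pick1(which(comp$membership == pick[1]))
    b <- pick1(which(comp$membership == pick[2]))
    g <- igraph::add_edges(g, c(a, b))
    comp <- igraph::components(g)
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(A) <- "double"
  A
}

plant_nn_module <- function(A) {
  v <- sample.int(nrow(A), 5)   # u, v, w1..w3
  u <- v[1]; w <- v[2]
  A[u, w] <- A[w, u] <- 1
  for (x in v[3:5]) {
    A[u, x] <- A[x, u] <- 1
    A[w, x] <- A[x, w] <- 1
  }
  A
}

plant_na_module <- function(A) {
  v <- sample.int(nrow(A), 7)   # h, x1..x4, chain end a, cycle vertex y
  h <- v[1]; x <- v[2:5]; a <- v[6]; yv <- v[7]
  for (xi in x) A[h, xi] <- A[xi, h] <- 1
  A[x[1], a] <- A[a, x[1]] <- 1          # pendant chain h - x1 - a
  A[x[3], yv] <- A[yv, x[3]] <- 1        # 4-cycle h - x3 - y - x4 - h
  A[x[4], yv] <- A[yv, x[4]] <- 1
  A
}

#' Generate a two-class synthetic cohort with planted motif differences
#'
#' Each network is a connected Erdos-Renyi-like graph at the target mean
#' degree.  `effect_size` modules are then planted per network: class +1
#' gets overlapping-triangle "book" modules (three triangles sharing one
#' edge), class -1 gets degree-4-6 hub modules with a pendant chain and a
#' vertex-joined but non-overlapping 4-cycle.  Both module types add the
#' same number of edges, and the base density is lowered to compensate, so
#' the two classes stay matched in mean degree while differing in subgraph
#' composition.  `effect_size = 0` yields two statistically identical
#' classes.
#'
#' @param n_per_class Networks per class (default 12, a 24-subject cohort).
#' @param n_nodes Nodes per network (default 100).
#' @param target_mean_degree Target mean degree (default 5.7).
#' @param effect_size Integer number of planted modules per network
#'   (default 0).
#' @param seed RNG seed; a fixed seed reproduces the cohort exactly.
#' @return List with `networks` (length `2 n_per_class`, class +1 first),
#'   `labels` (named, +1 then -1), and the generating parameters.
#' @export
generate_cohort <- function(n_per_class = 12, n_nodes = 100,
                            target_mean_degree = 5.7, effect_size = 0,
                            seed = 1) {
  if (n_per_class < 1 || n_nodes < 10) stop("cohort spec too small")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  effect_size <- as.integer(effect_size)
  m_target <- round(n_nodes * target_mean_degree / 2)
  m_base <- m_target - EDGES_PER_MODULE * effect_size
  if (m_base < n_nodes - 1)
    stop("infeasible spec: planted modules leave too few base edges for connectivity")
  labels <- rep(c(1, -1), each = n_per_class)
  ids <- sprintf("s%02d", seq_along(labels))
  names(labels) <- ids
  networks <- with_seed(seed, lapply(seq_along(labels), function(i) {
    A <- connected_gnm(n_nodes, m_base)
    for (k in seq_len(effect_size)) {
      A <- if (labels[i] > 0) plant_nn_module(A) else plant_na_module(A)
    }
    binary_network(A)
  }))
  names(networks) <- ids
  list(networks = networks, labels = labels,
       n_per_class = n_per_class, n_nodes = n_nodes,
       target_mean_degree = target_mean_degree,
       effect_size = effect_size, seed = seed)
}

#' Canonical keys of the subgraph classes targeted by the planted modules
#'
#' The class-+1 modules enrich triangle-bearing classes (triangle, paw,
#' diamond); the class--1 modules enrich the plain 4-cycle.  Returns the
#' keys of those motifs that are traceable at walk length `L` (i.e. present
#' in the length-L catalog), named by motif.
#'
#' @param L Walk length of the catalog in use.
#' @return Named character vector of canonical keys.
#' @export
planted_class_keys <- function(L) {
  motifs <- list(
    triangle = rbind(c(1, 2), c(2, 3), c(1, 3)),
    paw = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)),
    cycle4 = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
    diamond = rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4))
  )
  keep <- vapply(motifs, function(el) nrow(el) <= L && covering_walk_count(el, L) > 0,
                 logical(1))
  vapply(motifs[keep], canonical_key, "")
}

#' Attach positive weights to a binary network
#'
#' Draws an independent positive weight for every edge (a streamline-count
#' analog) so that thresholded binarization can be exercised:
#' `binarize(., 0)` recovers the input network exactly.
#'
#' @param net A [binary_network()].
#' @param law `"geometric"` (integer weights, mean `mean_weight`) or
#'   `"lognormal"` (continuous positive weights).
#' @param mean_weight Target mean edge weight (default 10).
#' @param seed RNG seed.
#' @return A [weighted_network()].
#' @export
generate_weighted <- function(net, law = c("geometric", "lognormal"),
                              mean_weight = 10, seed = 1) {
  stopifnot(inherits(net, "binary_network"))
  law <- match.arg(law)
  up <- which(upper.tri(net$A) & net$A != 0, arr.ind = TRUE)
  w <- with_seed(seed, switch(law,
    geometric = stats::rgeom(nrow(up), prob = 1 / mean_weight) + 1,
    lognormal = exp(stats::rnorm(nrow(up), mean = log(mean_weight), sd = 0.75))))
  W <- matrix(0, net$n, net$n)
  W[up] <- w
  W <- W + t(W)
  weighted_network(W, node_ids = net$node_ids)
}

#' Generate a network family for the resolution-selection rule
#'
#' Builds one network per grid value n: fully connected for `n <= n_star`,
#' and containing isolated nodes (so `n_G < n`) beyond `n_star`.  The
#' giant-component rule applied to this family recovers `n_star` exactly.
#'
#' @param n_star The planted optimal resolution; must belong to `n_grid`.
#' @param n_grid Strictly positive, distinct parcellation sizes.
#' @param target_mean_degree Mean degree of the connected part (default 5.7).
#' @param seed RNG seed.
#' @return List with `networks` (named by n), `n` (the grid, sorted) and
#'   `n_star`.
#' @export
generate_resolution_family <- function(n_star, n_grid, target_mean_degree = 5.7,
                                       seed = 1) {
  n_grid <- sort(unique(as.integer(n_grid)))
  if (length(n_grid) < 1 || any(n_grid < 10)) stop("invalid resolution grid")
  if (!n_star %in% n_grid) stop("n_star must be one of the grid values")
  networks <- with_seed(seed, lapply(n_grid, function(n) {
    if (n <= n_star) {
      A <- connected_gnm(n, round(n * target_mean_degree / 2))
    } else {
      n_conn <- n_star + floor(0.7 * (n - n_star))
      A <- matrix(0, n, n)
      A[seq_len(n_conn), seq_len(n_conn)] <-
        connected_gnm(n_conn, round(n_conn * target_mean_degree / 2))
    }
    binary_network(A)
  }))
  names(networks) <- as.character(n_grid)
  list(networks = networks, n = n_grid, n_star = as.integer(n_star))
}
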