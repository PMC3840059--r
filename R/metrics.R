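#' Node degrees
#'
#' Degree of node i is the row sum of the adjacency matrix: the number of
#' tracts incident on region i.
#'
#' @param net A [binary_network()].
#' @return Named integer vector of per-node degrees.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- as.integer(rowSums(net$A))
  names(d) <- net$node_ids
  d
}

#' Degree survival function P(d > d0)
#'
#' Fraction of nodes with degree strictly greater than `d0`, i.e. the
#' empirical complementary cumulative distribution of the degree sequence.
#' Vectorized over `d0`.
#'
#' @param net A [binary_network()].
#' @param d0 Numeric vector of degree cutoffs.
#' @return Numeric vector in `[0, 1]`, non-increasing in `d0`.
#' @export
degree_survival <- function(net, d0) {
  d <- node_degrees(net)
  vapply(d0, function(x) mean(d > x), numeric(1))
}

#' Local clustering coefficients and their mean
#'
#' `c_i = 2 e_i / (d_i (d_i - 1))` where `e_i` counts connected neighbor
#' pairs of node i (triangles through i).  Nodes of degree < 2 have no
#' neighbor pair and are assigned `c_i = 0`; the mean is taken over all n
#' nodes.
#'
#' @param net A [binary_network()].
#' @return List with `per_node` (named numeric vector) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$A
  d <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)   # 2 * (triangles through i) * ... = paths i->i of length 3
  ci <- ifelse(d >= 2, tri2 / (d * (d - 1)), 0)
  names(ci) <- net$node_ids
  list(per_node = ci, mean = mean(ci))
}

#' Mean geodesic length on the giant component
#'
#' Average shortest-path length over all unordered node pairs of the giant
#' (largest connected) component.  Restricting to the giant component keeps
#' the quantity defined when thresholding disconnects a network.
#'
#' @param net A [binary_network()].
#' @return A single number `>= 1`.
#' @export
mean_geodesic <- function(net) {
  gc <- giant_component(net)
  if (gc$size < 2) stop("mean geodesic is undefined: the giant component has fewer than 2 nodes")
  g <- as_igraph(net)
  D <- igraph::distances(g, v = gc$nodes, to = gc$nodes)
  mean(D[upper.tri(D)])
}

#' Transitivity T = 3t / q
#'
#' `t` is the number of distinct triangles and `q` the number of distinct
#' two-paths (a center node with an unordered pair of its neighbors).
#'
#' @param net A [binary_network()].
#' @return A single number in `[0, 1]`.
#' @export
graph_transitivity <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  A <- net$A
  d <- rowSums(A)
  t_count <- sum(diag(A %*% A %*% A)) / 6
  q_count <- sum(d * (d - 1) / 2)
  if (q_count == 0) stop("transitivity is undefined: the network has no two-paths")
  3 * t_count / q_count
}

#' Giant component of a network
#'
#' The largest connected component; among equally sized components the one
#' containing the smallest node index is returned, so the choice is
#' deterministic.
#'
#' @param net A [binary_network()].
#' @return List with `nodes` (integer indices, increasing), `size` (n_G).
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  comp <- igraph::components(as_igraph(net))
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    first_node <- vapply(best, function(k) min(which(comp$membership == k)), integer(1))
    best <- best[which.min(first_node)]
  }
  nodes <- unname(which(comp$membership == best))
  list(nodes = nodes, size = length(nodes))
}

#' Standard metric panel for one network
#'
#' Computes the degrees, mean degree, local and mean clustering, mean
#' geodesic length (giant component), transitivity and giant-component size
#' in one call.  Transitivity and the geodesic are `NA` where undefined
#' (no two-paths / giant component smaller than 2).
#'
#' @param net A [binary_network()].
#' @return An object of class `network_metrics`: a list with fields
#'   `degrees`, `mean_degree`, `clustering_per_node`, `mean_clustering`,
#'   `mean_geodesic`, `transitivity`, `giant_component_size`, `n`.
#' @export
network_metrics <- function(net) {
  d <- node_degrees(net)
  cl <- clustering_coefficient(net)
  gc <- giant_component(net)
  geo <- if (gc$size >= 2) mean_geodesic(net) else NA_real_
  tr <- if (sum(d * (d - 1)) > 0) graph_transitivity(net) else NA_real_
  structure(list(
    n = net$n,
    degrees = d,
    mean_degree = mean(d),
    clustering_per_node = cl$per_node,
    mean_clustering = cl$mean,
    mean_geodesic = geo,
    transitivity = tr,
    giant_component_size = gc$size
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "network_metrics: n = %d, mean degree = %.3f, mean clustering = %.3f,\n",
    "  mean geodesic = %s, transitivity = %s, giant component = %d\n"),
    x$n, x$mean_degree, x$mean_clustering,
    format(x$mean_geodesic, digits = 4), format(x$transitivity, digits = 4),
    x$giant_component_size))
  invisible(x)
}

#' Metric table for a cohort of networks
#'
#' One row per network: mean degree, mean clustering, mean geodesic,
#' transitivity, giant-component size.
#'
#' @param nets List of [binary_network()] objects.
#' @param ids Optional character vector of network ids.
#' @return A data frame with one row per network.
#' @export
metrics_table <- function(nets, ids = NULL) {
  if (is.null(ids)) ids <- names(nets)
  if (is.null(ids)) ids <- paste0("net", seq_along(nets))
  rows <- lapply(nets, function(nw) {
    m <- network_metrics(nw)
    data.frame(mean_degree = m$mean_degree,
               mean_clustering = m$mean_clustering,
               mean_geodesic = m$mean_geodesic,
               transitivity = m$transitivity,
               giant_component_size = m$giant_component_size,
               n = m$n)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(id = as.character(ids), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
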