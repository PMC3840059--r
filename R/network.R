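#' Construct a weighted network from a symmetric adjacency matrix
#'
#' A weighted network is the raw connectome object: a symmetric matrix of
#' nonnegative edge weights (e.g. streamline counts between brain regions),
#' with a zero diagonal (no self-loops).
#'
#' @param W Symmetric numeric matrix of nonnegative weights with zero
#'   diagonal.  Small asymmetries (up to `1e-9` relative) are symmetrized;
#'   anything larger is an error.
#' @param node_ids Optional character vector of node identifiers; defaults to
#'   the matrix dimnames or `"v1" ... "vn"`.
#' @return An object of class `weighted_network` with fields `n`, `W`,
#'   `node_ids`.
#' @seealso [binarize()], [binary_network()]
#' @export
weighted_network <- function(W, node_ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square")
  if (!is.numeric(W) || anyNA(W)) stop("adjacency matrix must be numeric with no missing values")
  asym <- max(abs(W - t(W)))
  scale <- max(abs(W), 1)
  if (asym > 1e-9 * scale) {
    stop(sprintf("adjacency matrix is not symmetric (max |W - t(W)| = %g)", asym))
  }
  W <- (W + t(W)) / 2
  if (any(W < 0)) stop("edge weights must be nonnegative")
  if (any(diag(W) != 0)) stop("diagonal must be zero (self-loops are not supported)")
  n <- nrow(W)
  node_ids <- resolve_node_ids(node_ids, W, n)
  dimnames(W) <- list(node_ids, node_ids)
  structure(list(n = n, W = W, node_ids = node_ids), class = "weighted_network")
}

#' Construct a binary network from a symmetric 0/1 adjacency matrix
#'
#' @param A Symmetric 0/1 matrix with zero diagonal.
#' @param node_ids Optional character vector of node identifiers.
#' @return An object of class `binary_network` with fields `n`, `A`,
#'   `node_ids`.
#' @export
binary_network <- function(A, node_ids = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (!all(A %in% c(0, 1))) stop("binary adjacency entries must be 0 or 1")
  storage.mode(A) <- "double"
  if (!identical(A, t(A))) stop("binary adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop("diagonal must be zero (self-loops are not supported)")
  n <- nrow(A)
  node_ids <- resolve_node_ids(node_ids, A, n)
  dimnames(A) <- list(node_ids, node_ids)
  structure(list(n = n, A = A, node_ids = node_ids), class = "binary_network")
}

resolve_node_ids <- function(node_ids, M, n) {
  if (is.null(node_ids)) {
    node_ids <- rownames(M)
    if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must equal the node count")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  node_ids
}

#' Binarize a weighted network at a strict threshold
#'
#' An edge is kept iff its weight is strictly greater than `tau`; `tau = 0`
#' keeps every positive-weight edge, the convention used to build binary
#' connectomes from streamline counts.
#'
#' @param net A [weighted_network()].
#' @param tau Nonnegative threshold; edges with weight `> tau` survive.
#' @return A [binary_network()] on the same nodes.
#' @export
binarize <- function(net, tau = 0) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("tau must be a single nonnegative number")
  }
  A <- (net$W > tau) * 1
  diag(A) <- 0
  binary_network(A, node_ids = net$node_ids)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges (positive weight)\n",
              x$n, sum(x$W[upper.tri(x$W)] > 0)))
  invisible(x)
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges\n",
              x$n, sum(x$A[upper.tri(x$A)])))
  invisible(x)
}

## igraph view of a binary network; used wherever standard graph algorithms
## (components, shortest paths, subgraph matching) are delegated to igraph.
as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$A, mode = "undirected", diag = FALSE)
}

## adjacency list on integer node indices (0 rows allowed)
adjacency_list <- function(net) {
  lapply(seq_len(net$n), function(i) which(net$A[i, ] != 0))
}
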