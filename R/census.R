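#' Canonical isomorphism key for a small simple graph
#'
#' Two graphs receive the same key iff they are isomorphic.  The graph is
#' relabeled with a canonical permutation (BLISS, via igraph) and the key is
#' the vertex count followed by the sorted canonical edge list, e.g.
#' `"3:1-2,1-3,2-3"` for a triangle.  Intended for the small subgraphs of a
#' walk census (at most 12 vertices).
#'
#' @param g An igraph graph, or a 2-column integer edge matrix.
#' @return A single character key.
#' @export
canonical_key <- function(g) {
  if (is.matrix(g)) g <- graph_from_edge_matrix(g)
  if (!igraph::is_igraph(g)) stop("g must be an igraph graph or a 2-column edge matrix")
  nv <- igraph::vcount(g)
  if (nv > 12) stop("graph too large for canonical_key (more than 12 vertices)")
  if (igraph::any_loop(g) || igraph::any_multiple(g)) stop("graph must be simple")
  perm <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(gc, names = FALSE)
  if (nrow(el) > 0) {
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  paste0(nv, ":", paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

## parse "v:1-2,1-3" back into an edge matrix + vertex count
parse_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  nv <- as.integer(parts[1])
  if (length(parts) < 2 || !nzchar(parts[2])) {
    return(list(n_vertices = nv, edges = matrix(integer(0), ncol = 2)))
  }
  prs <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  el <- matrix(as.integer(unlist(prs)), ncol = 2, byrow = TRUE)
  list(n_vertices = nv, edges = el)
}

graph_from_edge_matrix <- function(el, n_vertices = NULL) {
  el <- matrix(as.numeric(el), ncol = 2)
  if (is.null(n_vertices)) n_vertices <- if (nrow(el)) max(el) else 1
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < n_vertices)
      igraph::add_vertices(g, n_vertices - igraph::vcount(g)) else g)()
}

#' Count length-L walks inside a subgraph that cover all of its edges
#'
#' A covering walk is a vertex sequence `v_0 ... v_L` stepping along edges
#' of `h` whose traversed edge set equals the whole edge set of `h`.  Walks
#' may revisit vertices and re-use edges; a walk and its reversal count
#' separately.  This count is an isomorphism invariant of `h`, and it is the
#' per-instance factor of the factorized census: the number of length-L
#' walks in a host network tracing a given subgraph instance.
#'
#' Computed by dynamic programming over (current vertex, subset of covered
#' edges), `L` steps deep.
#'
#' @param edges 2-column integer edge matrix of a connected simple graph.
#' @param L Walk length (number of steps).
#' @return Integer count (0 when `h` has more than `L` edges).
#' @export
covering_walk_count <- function(edges, L) {
  el <- matrix(as.integer(edges), ncol = 2)
  ne <- nrow(el)
  if (L < 1) stop("L must be at least 1")
  if (ne == 0) stop("subgraph must have at least one edge")
  if (ne > L) return(0)
  if (ne > 25) stop("too many edges for subset dynamic programming")
  nv <- max(el)
  full <- bitwShiftL(1L, ne) - 1L
  ## dp[v, mask+1]: number of walks ending at v having covered exactly `mask`
  dp <- matrix(0, nrow = nv, ncol = bitwShiftL(1L, ne))
  dp[, 1] <- 1   # every vertex is a valid start
  ## incident edge list: for each vertex, (edge index, other endpoint)
  inc <- lapply(seq_len(nv), function(v) {
    hit <- which(el[, 1] == v | el[, 2] == v)
    cbind(edge = hit, to = ifelse(el[hit, 1] == v, el[hit, 2], el[hit, 1]))
  })
  for (step in seq_len(L)) {
    nxt <- matrix(0, nrow = nv, ncol = ncol(dp))
    for (v in seq_len(nv)) {
      masks <- which(dp[v, ] > 0)
      if (!length(masks)) next
      for (k in seq_len(nrow(inc[[v]]))) {
        e <- inc[[v]][k, 1]; u <- inc[[v]][k, 2]
        newmask <- bitwOr(masks - 1L, bitwShiftL(1L, e - 1L)) + 1L
        vals <- dp[v, masks]
        for (j in seq_along(masks)) nxt[u, newmask[j]] <- nxt[u, newmask[j]] + vals[j]
      }
    }
    dp <- nxt
  }
  sum(dp[, full + 1L])
}

#' Build the catalog of walk-traceable subgraph classes
#'
#' Enumerates every isomorphism class of simple graph traceable by a walk of
#' exactly `L` steps: abstract walks start at a single vertex and each step
#' either moves to an already-visited vertex (other than the current one) or
#' creates a fresh vertex; the set of traversed edges, up to isomorphism,
#' defines the class.  Enumeration is a breadth-first sweep over
#' (edge-set, current-vertex) states with first-appearance vertex labeling,
#' so the state space stays small.  For `L = 8` the catalog contains 149
#' classes.
#'
#' Each class carries its covering-walk count `W_L(H)` (see
#' [covering_walk_count()]), the factor used by the factorized census.
#' Classes are ordered by (edge count, vertex count, canonical key) so that
#' column indices of an embedding are stable across runs.
#'
#' @param L Walk length, between 1 and 10.
#' @return An object of class `subgraph_catalog`: list with `walk_length`,
#'   `classes` (data frame: `key`, `n_vertices`, `n_edges`,
#'   `covering_walks`), and `graphs` (list of igraph patterns in canonical
#'   labeling).
#' @export
build_catalog <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1) stop("L must be a positive integer")
  if (L > 10) stop("walk lengths above 10 are not supported")
  L <- as.integer(L)

  ## BFS over states (labeled edge set, current vertex); vertices labeled in
  ## order of first appearance, so identical states merge.
  states <- new.env(hash = TRUE, parent = emptyenv())
  assign("|1", list(edges = character(0), cur = 1L, k = 1L), envir = states)
  for (step in seq_len(L)) {
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (nm in ls(states)) {
      s <- get(nm, envir = states)
      if (s$k > 1L) {
        for (u in seq_len(s$k)) {
          if (u == s$cur) next
          e <- paste0(min(u, s$cur), "-", max(u, s$cur))
          edges <- if (e %in% s$edges) s$edges else sort(c(s$edges, e))
          kk <- paste0(paste(edges, collapse = ","), "|", u)
          if (!exists(kk, envir = nxt, inherits = FALSE))
            assign(kk, list(edges = edges, cur = u, k = s$k), envir = nxt)
        }
      }
      u <- s$k + 1L
      edges <- sort(c(s$edges, paste0(s$cur, "-", u)))
      kk <- paste0(paste(edges, collapse = ","), "|", u)
      if (!exists(kk, envir = nxt, inherits = FALSE))
        assign(kk, list(edges = edges, cur = u, k = u), envir = nxt)
    }
    states <- nxt
  }

  esets <- unique(vapply(ls(states), function(nm)
    paste(get(nm, envir = states)$edges, collapse = ","), ""))
  keys <- unique(vapply(esets, function(es) {
    canonical_key(edge_matrix_from_strings(es))
  }, "", USE.NAMES = FALSE))

  info <- lapply(keys, function(k) parse_key(k))
  nv <- vapply(info, `[[`, integer(1), "n_vertices")
  ne <- vapply(info, function(x) nrow(x$edges), integer(1))
  ord <- order(ne, nv, keys)
  keys <- keys[ord]; info <- info[ord]
  cw <- vapply(info, function(x) covering_walk_count(x$edges, L), numeric(1))
  stopifnot(all(cw >= 2))  # a walk and its reversal are distinct

  structure(list(
    walk_length = L,
    classes = data.frame(key = keys,
                         n_vertices = nv[ord],
                         n_edges = ne[ord],
                         covering_walks = cw,
                         stringsAsFactors = FALSE),
    graphs = lapply(info, function(x) graph_from_edge_matrix(x$edges, x$n_vertices))
  ), class = "subgraph_catalog")
}

edge_matrix_from_strings <- function(es) {
  prs <- strsplit(strsplit(es, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  matrix(as.integer(unlist(prs)), ncol = 2, byrow = TRUE)
}

#' @export
print.subgraph_catalog <- function(x, ...) {
  cat(sprintf("subgraph_catalog: walk length %d, %d isomorphism classes\n",
              x$walk_length, nrow(x$classes)))
  invisible(x)
}

#' Count instances of a subgraph class in a network
#'
#' An instance is a distinct edge subset of the network isomorphic to the
#' pattern (non-induced: extra adjacencies among the instance's vertices are
#' allowed and belong to other instances).  Counted as subgraph
#' monomorphisms (compiled backtracking search) divided by the pattern's
#' automorphism count.
#'
#' @param net A [binary_network()].
#' @param pattern An igraph pattern, 2-column edge matrix, or canonical key.
#' @return Number of instances (exact integer value, stored as double).
#' @export
count_subgraph_instances <- function(net, pattern) {
  p <- as_pattern_edges(pattern)
  host <- which(upper.tri(net$A) & net$A != 0, arr.ind = TRUE)
  if (p$n_vertices > net$n || nrow(p$edges) > nrow(host)) return(0)
  mono <- count_monomorphisms_cpp(p$edges, p$n_vertices, host, net$n)
  aut <- count_monomorphisms_cpp(p$edges, p$n_vertices, p$edges, p$n_vertices)
  mono / aut
}

## normalize a pattern (igraph / key / edge matrix) to an integer edge
## matrix plus vertex count
as_pattern_edges <- function(pattern) {
  if (igraph::is_igraph(pattern)) {
    el <- igraph::as_edgelist(pattern, names = FALSE)
    storage.mode(el) <- "integer"
    return(list(edges = el, n_vertices = igraph::vcount(pattern)))
  }
  if (is.character(pattern) && length(pattern) == 1L) {
    p <- parse_key(pattern)
    return(list(edges = p$edges, n_vertices = p$n_vertices))
  }
  if (is.matrix(pattern)) {
    el <- matrix(as.integer(pattern), ncol = 2)
    return(list(edges = el, n_vertices = max(el)))
  }
  stop("pattern must be an igraph graph, edge matrix, or canonical key")
}

#' Subgraph walk census of a network
#'
#' Counts, for every class in the catalog, the number of length-L walks in
#' the network whose traced edge set belongs to that class.  Two methods:
#'
#' * `"factorized"` (default): per class, (number of subgraph instances) x
#'   (covering-walk count of the class).  Scales to 100-node connectomes.
#' * `"direct"`: exhaustive enumeration of all length-L walks, classifying
#'   each traced edge set.  Exponential in L; retained as the small-instance
#'   oracle that the factorized method is validated against.
#'
#' Both methods agree exactly; counts are integer-valued (walk totals stay
#' far below 2^53, so double storage is exact).
#'
#' @param net A [binary_network()].
#' @param catalog A [build_catalog()] result.
#' @param method `"factorized"` or `"direct"`.
#' @return Named numeric vector of per-class walk counts, in catalog order.
#' @export
census_walk_counts <- function(net, catalog, method = c("factorized", "direct")) {
  stopifnot(inherits(net, "binary_network"), inherits(catalog, "subgraph_catalog"))
  method <- match.arg(method)
  counts <- switch(method,
    factorized = census_factorized(net, catalog),
    direct = census_direct(net, catalog))
  names(counts) <- catalog$classes$key
  counts
}

census_factorized <- function(net, catalog) {
  vapply(seq_len(nrow(catalog$classes)), function(i) {
    count_subgraph_instances(net, catalog$graphs[[i]]) * catalog$classes$covering_walks[i]
  }, numeric(1))
}

census_direct <- function(net, catalog) {
  L <- catalog$walk_length
  M <- nrow(catalog$classes)
  adj <- adjacency_list(net)
  deg <- lengths(adj)
  out <- numeric(M)
  if (sum(deg) == 0) return(out)
  ## expand all walks level by level; rows = partial walks
  walks <- matrix(which(deg > 0), ncol = 1)
  for (s in seq_len(L)) {
    cur <- walks[, ncol(walks)]
    reps <- deg[cur]
    walks <- walks[rep(seq_len(nrow(walks)), reps), , drop = FALSE]
    walks <- cbind(walks, unlist(adj[cur], use.names = FALSE))
  }
  ## tally by first-appearance-labeled traced edge set
  tallies <- new.env(hash = TRUE, parent = emptyenv())
  nsteps <- ncol(walks) - 1L
  for (r in seq_len(nrow(walks))) {
    w <- walks[r, ]
    lab <- integer(0); map <- integer(net$n)
    nxt <- 0L
    es <- character(nsteps)
    for (s in seq_len(nsteps + 1L)) {
      v <- w[s]
      if (map[v] == 0L) { nxt <- nxt + 1L; map[v] <- nxt }
      if (s > 1L) {
        a <- map[w[s - 1L]]; b <- map[v]
        es[s - 1L] <- paste0(min(a, b), "-", max(a, b))
      }
    }
    key <- paste(sort(unique(es)), collapse = ",")
    prev <- if (exists(key, envir = tallies, inherits = FALSE)) get(key, envir = tallies) else 0
    assign(key, prev + 1, envir = tallies)
  }
  ## canonicalize the distinct labeled edge sets and map to catalog columns
  idx <- stats::setNames(seq_len(M), catalog$classes$key)
  for (es in ls(tallies)) {
    ck <- canonical_key(edge_matrix_from_strings(es))
    j <- idx[ck]
    if (is.na(j)) stop(sprintf("traced class %s not present in the catalog (walk length mismatch?)", ck))
    out[j] <- out[j] + get(es, envir = tallies)
  }
  out
}

#' Total number of length-L walks in a network
#'
#' Closed form: the sum of all entries of `A^L`.  Used as a cross-check for
#' the census (the per-class counts must sum to this total).
#'
#' @param net A [binary_network()].
#' @param L Walk length.
#' @return Total walk count.
#' @export
total_walk_count <- function(net, L) {
  stopifnot(inherits(net, "binary_network"), L >= 1)
  P <- net$A
  for (i in seq_len(L - 1)) P <- P %*% net$A
  sum(P)
}

#' Embed a cohort of networks in subgraph-census space
#'
#' Row i is the walk census of network i; columns follow the catalog order,
#' named by canonical key.  The result is the `N x M` data matrix fed to PCA
#' and classification (24 x 149 in the walk-length-8 connectome setting).
#'
#' @param nets Nonempty list of [binary_network()] objects.
#' @param catalog A [build_catalog()] result.
#' @param method Census method, see [census_walk_counts()].
#' @param ids Optional row ids (defaults to `names(nets)`).
#' @return Numeric matrix with one row per network.
#' @export
embed_cohort <- function(nets, catalog, method = c("factorized", "direct"), ids = NULL) {
  if (length(nets) == 0) stop("cohort must contain at least one network")
  method <- match.arg(method)
  X <- t(vapply(nets, census_walk_counts, numeric(nrow(catalog$classes)),
                catalog = catalog, method = method))
  if (is.null(ids)) ids <- names(nets)
  if (is.null(ids)) ids <- paste0("net", seq_along(nets))
  rownames(X) <- ids
  colnames(X) <- catalog$classes$key
  X
}
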