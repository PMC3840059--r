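#' Read a network from a file
#'
#' Supported formats:
#' * `"matrix"`: whitespace- or comma-delimited n x n numeric text, with an
#'   optional first row of node ids (detected when the first row is
#'   non-numeric).  Node order in the file is authoritative.
#' * `"edgelist"`: one `node_a node_b weight` triple per line (comma or
#'   whitespace separated; weight optional, default 1).  An optional leading
#'   comment line `# nodes: a b c ...` declares the full node set, so
#'   isolated nodes survive the round trip.
#' * `"graphml"`: GraphML interchange (edge attribute `weight`, default 1).
#'
#' @param path File path.
#' @param format One of `"auto"`, `"matrix"`, `"edgelist"`, `"graphml"`;
#'   `"auto"` decides by file extension (`.graphml`, `.edges`/`.edgelist`,
#'   otherwise matrix).
#' @return A [weighted_network()].
#' @export
read_network <- function(path, format = c("auto", "matrix", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
      else if (grepl("\\.(edges|edgelist)$", path, ignore.case = TRUE)) "edgelist"
      else "matrix"
  }
  switch(format,
    matrix = read_network_matrix(path),
    edgelist = read_network_edgelist(path),
    graphml = read_network_graphml(path))
}

split_fields <- function(line) {
  strsplit(trimws(line), "[,\t ]+")[[1]]
}

read_network_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty network file: ", path)
  first <- split_fields(lines[1])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  ids <- if (has_header) first else NULL
  body <- if (has_header) lines[-1] else lines
  rows <- lapply(body, function(l) {
    x <- suppressWarnings(as.numeric(split_fields(l)))
    if (anyNA(x)) stop("non-numeric entry in adjacency matrix: ", path)
    x
  })
  if (length(unique(lengths(rows))) != 1) stop("ragged adjacency matrix: ", path)
  W <- do.call(rbind, rows)
  if (nrow(W) != ncol(W)) stop("adjacency matrix is not square: ", path)
  weighted_network(W, node_ids = ids)
}

read_network_edgelist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ids <- NULL
  header <- grepl("^#\\s*nodes\\s*:", lines, ignore.case = TRUE)
  if (any(header)) {
    ids <- split_fields(sub("^#\\s*nodes\\s*:", "", lines[which(header)[1]], ignore.case = TRUE))
  }
  lines <- lines[!grepl("^#", lines)]
  recs <- lapply(lines, split_fields)
  a <- vapply(recs, `[`, "", 1)
  b <- vapply(recs, `[`, "", 2)
  w <- vapply(recs, function(r) if (length(r) >= 3) as.numeric(r[3]) else 1, numeric(1))
  if (anyNA(w)) stop("non-numeric edge weight in ", path)
  if (is.null(ids)) ids <- unique(c(rbind(a, b)))
  if (!all(c(a, b) %in% ids)) stop("edge endpoint not in declared node set: ", path)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_along(a)) {
    W[a[k], b[k]] <- w[k]
    W[b[k], a[k]] <- w[k]
  }
  weighted_network(W, node_ids = ids)
}

read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE))
  ids <- if ("name" %in% igraph::vertex_attr_names(g)) igraph::V(g)$name else NULL
  weighted_network(W, node_ids = ids)
}

#' Write a network to a file
#'
#' Matrix format writes a tab-delimited adjacency matrix with a node-id
#' header row; edge-list format writes a `# nodes:` declaration followed by
#' upper-triangle edges; GraphML goes through igraph.
#'
#' @param net A [weighted_network()] or [binary_network()].
#' @param path Output path.
#' @param format `"matrix"`, `"edgelist"` or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("matrix", "edgelist", "graphml")) {
  format <- match.arg(format)
  M <- if (inherits(net, "weighted_network")) net$W else net$A
  ids <- net$node_ids
  if (format == "matrix") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(ids, collapse = "\t"), con)
    utils::write.table(M, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else if (format == "edgelist") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste("# nodes:", paste(ids, collapse = " ")), con)
    up <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
    if (nrow(up)) {
      writeLines(paste(ids[up[, 1]], ids[up[, 2]], M[up], sep = "\t"), con)
    }
  } else {
    g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected", weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- ids
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read class labels for a cohort
#'
#' CSV with two columns, subject id and class; classes must be coded -1
#' (abnormal) or 1 (normal).  A header line is detected and skipped.
#'
#' @param path File path.
#' @return Named integer vector of labels in file order.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, split_fields)
  if (length(recs) && anyNA(suppressWarnings(as.numeric(recs[[1]][2])))) recs <- recs[-1]
  ids <- vapply(recs, `[`, "", 1)
  y <- suppressWarnings(as.numeric(vapply(recs, `[`, "", 2)))
  if (anyNA(y) || !all(y %in% c(-1, 1)))
    stop("labels must be -1 or 1 (got: ", paste(unique(y), collapse = ", "), ")")
  stats::setNames(as.integer(y), ids)
}

#' Write a report object as JSON
#'
#' Full-precision, auto-unboxed JSON; the canonical machine-readable output
#' of the pipeline.
#'
#' @param report Any list-like report.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Serialize / restore a subgraph catalog as JSON
#'
#' @param catalog A [build_catalog()] result.
#' @param path File path.
#' @return `read_catalog` returns a `subgraph_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "subgraph_catalog"))
  obj <- list(
    walk_length = catalog$walk_length,
    classes = lapply(seq_len(nrow(catalog$classes)), function(i) {
      p <- parse_key(catalog$classes$key[i])
      list(key = catalog$classes$key[i],
           n_vertices = catalog$classes$n_vertices[i],
           n_edges = catalog$classes$n_edges[i],
           covering_walks = catalog$classes$covering_walks[i],
           edges = unname(split(p$edges, row(p$edges))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  keys <- vapply(obj$classes, `[[`, "", "key")
  info <- lapply(keys, parse_key)
  structure(list(
    walk_length = as.integer(obj$walk_length),
    classes = data.frame(
      key = keys,
      n_vertices = vapply(obj$classes, function(x) as.integer(x$n_vertices), integer(1)),
      n_edges = vapply(obj$classes, function(x) as.integer(x$n_edges), integer(1)),
      covering_walks = vapply(obj$classes, function(x) as.numeric(x$covering_walks), numeric(1)),
      stringsAsFactors = FALSE),
    graphs = lapply(info, function(x) graph_from_edge_matrix(x$edges, x$n_vertices))
  ), class = "subgraph_catalog")
}

#' Write an embedding matrix as CSV
#'
#' Rows are subjects, columns are canonical subgraph keys.
#'
#' @param X Embedding matrix from [embed_cohort()].
#' @param path Output path.
#' @export
write_embedding <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
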