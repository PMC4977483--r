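#' Undirected PPI graph
#'
#' An undirected, unweighted graph over a fixed node universe, stored as a
#' sorted vector of node identifiers plus a symmetric sparse 0/1 adjacency
#' matrix. All matrices in the package (kernels, fusions, scores) share the
#' lexicographic node indexing established here, so positions are comparable
#' across objects.
#'
#' @param edges A data frame whose first two columns hold the endpoint
#'   identifiers of each undirected edge (coerced to character). Duplicate
#'   edges (in either orientation) are collapsed; self-loops are dropped with
#'   a warning.
#' @param nodes Optional character vector of node identifiers making up the
#'   universe; defaults to the identifiers seen in `edges`. Must cover every
#'   edge endpoint. Isolated nodes are allowed.
#'
#' @return An object of class `ppi_graph` with elements `node_ids`
#'   (character, sorted) and `adjacency` (sparse symmetric 0/1 matrix with
#'   zero diagonal, dimnames = node ids).
#' @examples
#' g <- ppi_graph(tibble::tibble(from = c("a", "b"), to = c("b", "c")))
#' graph_edges(g)
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) abort("`edges` needs two endpoint columns.")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  if (is.null(nodes)) nodes <- c(from, to) # loop endpoints stay in the universe
  loops <- from == to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  nodes <- sort(unique(as.character(nodes)), method = "radix")
  if (!all(c(from, to) %in% nodes)) {
    abort("every edge endpoint must be listed in `nodes`")
  }
  # canonical orientation (smaller index first) + dedup
  i <- match(from, nodes)
  j <- match(to, nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- !duplicated(lo * (length(nodes) + 1) + hi)
  lo <- lo[key]
  hi <- hi[key]
  n <- length(nodes)
  adj <- sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = 1,
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  adj@x[] <- 1 # in case both orientations appeared
  structure(
    list(node_ids = nodes, adjacency = adj),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf(
    "<ppi_graph> %d nodes, %d edges\n",
    length(x$node_ids), n_edges(x)
  ))
  invisible(x)
}

#' Graph accessors
#'
#' @param g A [ppi_graph].
#' @return `graph_nodes()`: character vector of node ids; `graph_edges()`: a
#'   tibble with columns `from`, `to` (from < to lexicographically);
#'   `n_edges()`: edge count; `node_degrees()`: tibble of `node`, `degree`.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
graph_nodes <- function(g) g$node_ids

#' @rdname graph-accessors
#' @export
graph_edges <- function(g) {
  m <- g$adjacency
  idx <- Matrix::which(Matrix::triu(m, k = 1) != 0, arr.ind = TRUE)
  out <- tibble(
    from = g$node_ids[idx[, 1]],
    to = g$node_ids[idx[, 2]]
  )
  arrange(out, .data$from, .data$to)
}

#' @rdname graph-accessors
#' @export
n_edges <- function(g) as.integer(sum(g$adjacency) / 2)

#' @rdname graph-accessors
#' @export
node_degrees <- function(g) {
  tibble(node = g$node_ids, degree = as.integer(Matrix::rowSums(g$adjacency)))
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Read an undirected edge list
#'
#' Reads a tab-separated two-column edge list (lines starting with `#` are
#' comments), deduplicates undirected edges and drops self-loops with a
#' warning.
#'
#' @param path Path to a TSV file with two identifier columns per line.
#' @return A [ppi_graph].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) abort(sprintf("no edges found in '%s'", path))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    lineno <- which(keep)[which(bad)[1]]
    abort(sprintf(
      "malformed edge list '%s': line %d does not have 2 tab-separated columns",
      path, lineno
    ))
  }
  ppi_graph(tibble(
    from = vapply(parts, `[[`, "", 1),
    to = vapply(parts, `[[`, "", 2)
  ))
}

#' Write an edge list as two-column TSV
#'
#' @param g A [ppi_graph] or a tibble with `from`/`to` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  edges <- if (inherits(g, "ppi_graph")) graph_edges(g) else g
  writeLines(paste(edges[[1]], edges[[2]], sep = "\t"), path)
  invisible(path)
}

#' Hop distances from a start node
#'
#' Breadth-first shortest-path (hop) distances from `s` to every node in the
#' universe; unreachable nodes get `Inf`.
#'
#' @param g A [ppi_graph].
#' @param s A node identifier present in `g`.
#' @return Named numeric vector of hop counts over all nodes.
#' @export
bfs_distances <- function(g, s) {
  if (!s %in% g$node_ids) abort(sprintf("node '%s' not in graph", s))
  d <- igraph::distances(as_igraph(g), v = s, mode = "all")[1, ]
  setNames(as.numeric(d), g$node_ids)
}

#' Highest-degree nodes
#'
#' The `k` nodes of largest degree, in descending degree order; ties are
#' broken by lexicographic node id so the ranking is deterministic.
#'
#' @param g A [ppi_graph].
#' @param k Number of hubs requested; must not exceed the node count.
#' @return Character vector of `k` node ids.
#' @export
top_hubs <- function(g, k) {
  if (k > length(g$node_ids)) {
    abort(sprintf("k = %d exceeds node count %d", k, length(g$node_ids)))
  }
  deg <- node_degrees(g)
  ord <- order(-deg$degree, deg$node, method = "radix")
  deg$node[ord][seq_len(k)]
}

#' Near/middle/far node partition around a start node
#'
#' Splits the nodes reachable from `s` into the near set D (hop distance
#' strictly below `eps1`), the far set L (distance strictly above `eps2`) and
#' the middle set M (the rest). The start node itself belongs to none of the
#' three sets, and unreachable nodes are excluded entirely. D and L supply
#' the training pairs for weight fitting; M is the held-out set.
#'
#' @param g A [ppi_graph].
#' @param s Start node id.
#' @param eps1,eps2 Integer hop thresholds, `0 < eps1 <= eps2`.
#' @return A `node_partition`: list with `source`, `near`, `far`, `middle`,
#'   `eps1`, `eps2`.
#' @export
partition_nodes <- function(g, s, eps1, eps2) {
  if (!s %in% g$node_ids) abort(sprintf("node '%s' not in graph", s))
  if (eps1 <= 0 || eps1 > eps2) abort("need 0 < eps1 <= eps2")
  d <- bfs_distances(g, s)
  d <- d[names(d) != s]
  reach <- names(d)[is.finite(d)]
  dr <- d[reach]
  node_partition(
    source = s,
    near = reach[dr < eps1],
    far = reach[dr > eps2],
    middle = reach[dr >= eps1 & dr <= eps2],
    eps1 = eps1, eps2 = eps2
  )
}

#' Construct a node partition directly
#'
#' Low-level constructor used by [partition_nodes()] and by tests/harnesses
#' that need a hand-built partition (e.g. training on every node pair).
#'
#' @param source Start node id.
#' @param near,far,middle Disjoint character vectors of node ids.
#' @param eps1,eps2 The hop thresholds the sets were built with.
#' @return A `node_partition`.
#' @export
node_partition <- function(source, near, far, middle, eps1 = NA_integer_,
                           eps2 = NA_integer_) {
  sets <- c(near, far, middle)
  if (anyDuplicated(sets) > 0) abort("partition sets must be disjoint")
  if (source %in% sets) abort("source node cannot be in D/L/M")
  structure(
    list(
      source = source, near = near, far = far, middle = middle,
      eps1 = eps1, eps2 = eps2
    ),
    class = "node_partition"
  )
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf(
    "<node_partition> s=%s |D|=%d |M|=%d |L|=%d (eps1=%s, eps2=%s)\n",
    x$source, length(x$near), length(x$middle), length(x$far),
    x$eps1, x$eps2
  ))
  invisible(x)
}

#' Keep node pairs whose endpoints are far apart in a graph
#'
#' Retains pairs whose shortest-path distance in `g_train` is strictly
#' greater than `min_dist`. Pairs whose endpoints fall in different
#' components (infinite distance) are treated as far apart and retained.
#'
#' @param g_train A [ppi_graph] (typically the training network).
#' @param pairs Tibble/data frame with two id columns.
#' @param min_dist Integer distance threshold.
#' @return The retained rows of `pairs`, as a tibble.
#' @export
pair_distance_filter <- function(g_train, pairs, min_dist) {
  pairs <- as_tibble(as.data.frame(pairs))
  if (nrow(pairs) == 0) return(pairs)
  u <- as.character(pairs[[1]])
  v <- as.character(pairs[[2]])
  if (!all(c(u, v) %in% g_train$node_ids)) {
    abort("pair endpoints must belong to the graph's node universe")
  }
  us <- unique(u)
  d <- igraph::distances(as_igraph(g_train), v = us, mode = "all")
  dist_uv <- d[cbind(match(u, us), match(v, g_train$node_ids))]
  pairs[dist_uv > min_dist, , drop = FALSE]
}
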