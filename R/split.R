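#' Golden-standard edge splits
#'
#' A split of a graph's edge set into training, validation and test edges.
#' `split_golden()` keeps the training network connected (over the nodes it
#' still touches) by removing sampled edges one at a time and skipping any
#' edge whose removal would disconnect the current training graph;
#' `random_edge_split()` splits uniformly with no connectivity requirement
#' (the variant used for originally disconnected networks).
#'
#' @param g A [ppi_graph]; for `split_golden()` it must be connected.
#' @param n_validation,n_test Number of edges to reserve.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return An `edge_split`: list with tibbles `train`, `validation`, `test`
#'   (columns `from`, `to`), flag `connected_train` and the `seed`.
#' @examples
#' g <- copying_model(30, seed = 1)
#' sp <- split_golden(g, n_validation = 3, n_test = 6, seed = 2)
#' nrow(sp$train)
#' @export
split_golden <- function(g, n_validation, n_test, seed) {
  n_remove <- n_validation + n_test
  edges <- graph_edges(g)
  if (n_remove >= nrow(edges)) {
    abort("n_validation + n_test must be smaller than the edge count")
  }
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  touched <- which(igraph::degree(ig) > 0)
  if (length(unique(comp$membership[touched])) > 1) {
    abort("`g` must be connected; use random_edge_split() for disconnected graphs")
  }
  order_idx <- withr::with_seed(seed, sample.int(nrow(edges)))
  removed <- integer(0)
  for (cand in order_idx) {
    if (length(removed) == n_remove) break
    eid <- igraph::get_edge_ids(ig, c(edges$from[cand], edges$to[cand]))
    ig2 <- igraph::delete_edges(ig, eid)
    if (.edges_connected(ig2, touched)) {
      ig <- ig2
      removed <- c(removed, cand)
    }
  }
  if (length(removed) < n_remove) {
    abort(sprintf(
      "cannot remove %d edges while keeping the training network connected (only %d removable)",
      n_remove, length(removed)
    ))
  }
  test_idx <- removed[seq_len(n_test)]
  val_idx <- removed[n_test + seq_len(n_validation)]
  new_edge_split(
    train = edges[-removed, , drop = FALSE],
    validation = edges[val_idx, , drop = FALSE],
    test = edges[test_idx, , drop = FALSE],
    connected_train = TRUE,
    seed = seed
  )
}

# connectivity over the node set the source graph started with: an edge
# removal that isolates a previously connected node counts as disconnecting
.edges_connected <- function(ig, touched) {
  sub <- igraph::induced_subgraph(ig, touched)
  igraph::vcount(sub) == 0 || igraph::is_connected(sub)
}

#' @rdname split_golden
#' @export
random_edge_split <- function(g, n_test, seed) {
  edges <- graph_edges(g)
  if (n_test >= nrow(edges)) abort("n_test must be smaller than the edge count")
  test_idx <- withr::with_seed(seed, sample.int(nrow(edges), n_test))
  new_edge_split(
    train = edges[setdiff(seq_len(nrow(edges)), test_idx), , drop = FALSE],
    validation = edges[integer(0), , drop = FALSE],
    test = edges[test_idx, , drop = FALSE],
    connected_train = FALSE,
    seed = seed
  )
}

new_edge_split <- function(train, validation, test, connected_train, seed) {
  structure(
    list(
      train = as_tibble(train), validation = as_tibble(validation),
      test = as_tibble(test), connected_train = connected_train, seed = seed
    ),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf(
    "<edge_split> train %d / validation %d / test %d edges (connected_train=%s)\n",
    nrow(x$train), nrow(x$validation), nrow(x$test), x$connected_train
  ))
  invisible(x)
}

#' Training graph of a split
#'
#' Builds the [ppi_graph] spanned by a split's training edges over the full
#' node universe of the source graph (so matrices stay index-compatible).
#'
#' @param split An `edge_split`.
#' @param g The source [ppi_graph] the split was made from.
#' @return A [ppi_graph] over `graph_nodes(g)` with only the training edges.
#' @export
train_graph <- function(split, g) {
  ppi_graph(split$train, nodes = graph_nodes(g))
}

#' Serialize a split to three edge-list TSVs plus a JSON manifest
#'
#' @param split An `edge_split`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_edge_split <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(split$train, file.path(dir, "train.tsv"))
  write_edge_list(split$validation, file.path(dir, "validation.tsv"))
  write_edge_list(split$test, file.path(dir, "test.tsv"))
  jsonlite::write_json(
    list(
      seed = split$seed,
      counts = list(
        train = nrow(split$train), validation = nrow(split$validation),
        test = nrow(split$test)
      ),
      connected_train = split$connected_train
    ),
    file.path(dir, "split.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
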