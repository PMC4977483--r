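# Small graph builders and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the package's own machinery (igraph,
# rank-based AUC) so that agreement is evidence, not tautology.

path_graph <- function(ids) {
  ppi_graph(tibble::tibble(from = ids[-length(ids)], to = ids[-1]))
}

star_graph <- function(center, leaves) {
  ppi_graph(tibble::tibble(from = center, to = leaves))
}

triangle_graph <- function(ids = c("a", "b", "c")) {
  ppi_graph(tibble::tibble(
    from = ids[c(1, 2, 3)], to = ids[c(2, 3, 1)]
  ))
}

# plain-R breadth-first hop distances over an edge tibble
bfs_oracle <- function(edges, nodes, s) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[[1]][i]
    b <- edges[[2]][i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# union-find connectivity over the nodes touched by the edges
connected_oracle <- function(edges) {
  nodes <- unique(c(edges[[1]], edges[[2]]))
  if (length(nodes) <= 1) {
    return(TRUE)
  }
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[[1]][i])
    rb <- find(edges[[2]][i])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(nodes, find, ""))) == 1
}

# brute-force Mann-Whitney AUC with half-credit ties
brute_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# random symmetric feature kernel over a graph's nodes
random_kernel <- function(g, name, seed) {
  n <- length(graph_nodes(g))
  m <- withr::with_seed(seed, matrix(runif(n * n), n, n))
  m <- (m + t(m)) / 2
  dimnames(m) <- list(graph_nodes(g), graph_nodes(g))
  feature_kernel(m, name)
}

# square score matrix from a pair -> value map (unlisted pairs get 0)
pair_score_matrix <- function(nodes, pairs, values) {
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_along(values)) {
    m[pairs[[1]][i], pairs[[2]][i]] <- values[i]
    m[pairs[[2]][i], pairs[[1]][i]] <- values[i]
  }
  m
}
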