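test_that("edge lists are read with dedup, self-loop dropping and sorted ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\ta", "c\tc"), f)
  expect_warning(g <- read_edge_list(f), "self-loop")
  expect_equal(graph_nodes(g), c("a", "b", "c"))
  expect_equal(graph_edges(g), tibble::tibble(from = "a", to = "b"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "p1\tp2", "p2\tp3"), f2)
  g2 <- read_edge_list(f2)
  expect_equal(length(graph_nodes(g2)), 3)
  expect_equal(n_edges(g2), 2)
  expect_true(Matrix::isSymmetric(g2$adjacency))
  expect_true(all(Matrix::diag(g2$adjacency) == 0))
})

test_that("malformed and empty edge lists are rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a", f)
  expect_error(read_edge_list(f), "line 1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f2)
  expect_error(read_edge_list(f2), "no edges")
})

test_that("edge list round-trips through write_edge_list", {
  g <- copying_model(40, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  expect_equal(graph_edges(g2), graph_edges(g))
})

test_that("golden split keeps the training network connected", {
  tri <- triangle_graph()
  sp <- split_golden(tri, n_validation = 0, n_test = 1, seed = 1)
  expect_equal(nrow(sp$train), 2)
  expect_equal(nrow(sp$test), 1)
  expect_true(sp$connected_train)
  expect_true(connected_oracle(sp$train))

  # both edges of a 3-path are bridges: nothing is removable
  pg <- path_graph(c("a", "b", "c"))
  expect_error(split_golden(pg, 0, 1, seed = 1), "connected")
})

test_that("golden split has exact sizes and reconstructs the edge set", {
  g <- copying_model(200, seed = 4)
  sp <- split_golden(g, n_validation = 20, n_test = 60, seed = 9)
  expect_equal(nrow(sp$validation), 20)
  expect_equal(nrow(sp$test), 60)
  expect_equal(nrow(sp$train), n_edges(g) - 80)
  expect_true(connected_oracle(sp$train))
  key <- function(e) sort(paste(e$from, e$to))
  expect_equal(
    sort(c(key(sp$train), key(sp$validation), key(sp$test))),
    key(graph_edges(g))
  )
  # determinism
  sp2 <- split_golden(g, n_validation = 20, n_test = 60, seed = 9)
  expect_identical(sp, sp2)
})

test_that("golden split properties hold across many seeds", {
  g <- copying_model(80, seed = 7)
  key <- function(e) sort(paste(e$from, e$to))
  all_edges <- key(graph_edges(g))
  for (seed in 1:25) {
    sp <- split_golden(g, n_validation = 5, n_test = 15, seed = seed)
    expect_equal(sort(c(key(sp$train), key(sp$validation), key(sp$test))), all_edges)
    expect_true(connected_oracle(sp$train))
  }
})

test_that("random edge split partitions the edges with no connectivity demand", {
  g <- copying_model(30, seed = 3)
  sp <- random_edge_split(g, n_test = 4, seed = 5)
  expect_false(sp$connected_train)
  expect_equal(nrow(sp$validation), 0)
  expect_equal(nrow(sp$test), 4)
  expect_equal(nrow(sp$train) + 4, n_edges(g))
  key <- function(e) sort(paste(e$from, e$to))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)

  sp0 <- random_edge_split(g, n_test = 0, seed = 5)
  expect_equal(nrow(sp0$train), n_edges(g))
  expect_identical(
    random_edge_split(g, 4, seed = 11),
    random_edge_split(g, 4, seed = 11)
  )
  expect_error(random_edge_split(g, n_edges(g), seed = 1), "smaller")
})

test_that("top hubs come in degree order with lexicographic ties", {
  st <- star_graph("c", c("w", "x", "y", "z"))
  expect_equal(top_hubs(st, 1), "c")

  pg <- path_graph(c("a", "b", "c"))
  expect_equal(top_hubs(pg, 2), c("b", "a"))

  g <- copying_model(50, seed = 1)
  hubs <- top_hubs(g, length(graph_nodes(g)))
  degs <- node_degrees(g)
  expect_equal(sort(hubs), sort(graph_nodes(g)))
  expect_true(all(diff(degs$degree[match(hubs, degs$node)]) <= 0))
  expect_error(top_hubs(pg, 4), "exceeds")
})

test_that("node partition follows BFS hop thresholds", {
  pg <- path_graph(c("s", "a", "b", "c", "d"))
  part <- partition_nodes(pg, "s", eps1 = 2, eps2 = 3)
  expect_equal(part$near, "a")
  expect_equal(sort(part$middle), c("b", "c"))
  expect_equal(part$far, "d")

  # eps1 = 1: no node is strictly closer than 1 hop (s itself is excluded)
  p1 <- partition_nodes(pg, "s", eps1 = 1, eps2 = 2)
  expect_length(p1$near, 0)

  # isolated node is unreachable and lands in no set
  g <- ppi_graph(tibble::tibble(from = "a", to = "b"), nodes = c("a", "b", "z"))
  pz <- partition_nodes(g, "a", 1, 1)
  expect_false("z" %in% c(pz$near, pz$middle, pz$far))

  expect_error(partition_nodes(pg, "nope", 1, 2), "not in graph")
  expect_error(partition_nodes(pg, "s", 3, 2), "eps1")
})

test_that("partition covers the node set disjointly", {
  g <- copying_model(120, seed = 6)
  d <- bfs_distances(g, "v001")
  for (eps in list(c(1, 2), c(2, 4), c(3, 3))) {
    part <- partition_nodes(g, "v001", eps[1], eps[2])
    sets <- c(part$near, part$middle, part$far)
    expect_equal(anyDuplicated(sets), 0)
    unreachable <- names(d)[is.infinite(d)]
    expect_setequal(
      c(sets, "v001", unreachable),
      graph_nodes(g)
    )
  }
})

test_that("partition distances agree with a hand BFS oracle", {
  g <- copying_model(60, seed = 9)
  d_pkg <- bfs_distances(g, "v03")
  d_orc <- bfs_oracle(graph_edges(g), graph_nodes(g), "v03")
  expect_equal(d_pkg, d_orc)
})

test_that("distance filter keeps far pairs, including cross-component ones", {
  pg <- path_graph(c("a", "b", "c", "d", "e"))
  pairs <- tibble::tibble(from = c("a", "a"), to = c("e", "b"))
  kept <- pair_distance_filter(pg, pairs, min_dist = 3)
  expect_equal(kept, tibble::tibble(from = "a", to = "e"))

  two <- ppi_graph(
    tibble::tibble(from = c("a", "x"), to = c("b", "y"))
  )
  cross <- tibble::tibble(from = "a", to = "y")
  expect_equal(nrow(pair_distance_filter(two, cross, 3)), 1)
  expect_error(
    pair_distance_filter(two, tibble::tibble(from = "a", to = "q"), 3),
    "universe"
  )
})
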