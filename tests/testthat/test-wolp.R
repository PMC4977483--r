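# helper: a small graph with two dense kernels over its nodes
small_setup <- function(n = 30, seed = 1, n_kernels = 2) {
  g <- copying_model(n, seed = seed)
  ks <- lapply(seq_len(n_kernels), function(i) {
    random_kernel(g, paste0("k", i), 100 * seed + i)
  })
  list(g = g, ks = ks)
}

test_that("the constraint system enumerates qualifying triangle pairs", {
  su <- small_setup(10, seed = 2)
  p <- rwr_distribution(to_transition(su$g), "v01")
  part <- node_partition("v01",
    near = c("v02", "v03"), far = "v09",
    middle = character(0)
  )
  qb <- barker_matrix(p, support = c("v02", "v03", "v09"))
  sys <- build_system(qb, su$g, su$ks, part, mapping = "lower")
  expect_lte(nrow(sys$X), 3) # at most |D ∪ L| choose 2
  expect_equal(colnames(sys$X), c("G_tn", "k1", "k2"))
  expect_true(all(sys$pairs$u < sys$pairs$v))
  expect_equal(sys$rhs, qb[cbind(sys$pairs$u, sys$pairs$v)])
})

test_that("lower and upper mappings share coefficients but swap the rhs", {
  su <- small_setup(12, seed = 3)
  p <- rwr_distribution(to_transition(su$g), "v01")
  part <- node_partition("v01",
    near = c("v02", "v04"), far = c("v10", "v11"),
    middle = character(0)
  )
  qb <- barker_matrix(p, support = c(part$near, part$far))
  lo <- build_system(qb, su$g, su$ks, part, mapping = "lower", coefficients = "raw")
  up <- build_system(qb, su$g, su$ks, part, mapping = "upper", coefficients = "raw")
  # symmetric kernels: identical coefficient magnitudes, mirrored rhs
  expect_equal(lo$X, up$X, ignore_attr = TRUE)
  expect_equal(lo$rhs + up$rhs, rep(1, length(lo$rhs)), tolerance = 1e-14)
})

test_that("pairs with no support in any source are omitted", {
  g <- ppi_graph(tibble::tibble(from = c("a", "c"), to = c("b", "d")))
  zero <- matrix(0, 4, 4, dimnames = list(graph_nodes(g), graph_nodes(g)))
  zero["a", "b"] <- zero["b", "a"] <- 1
  k <- feature_kernel(zero, "kz", scale = FALSE)
  part <- node_partition("a",
    near = c("b", "c"), far = "d", middle = character(0)
  )
  p <- setNames(rep(0.25, 4), graph_nodes(g))
  qb <- barker_matrix(p, support = c("b", "c", "d"))
  sys <- build_system(qb, g, list(k), part, mapping = "lower")
  # of the pairs {b,c},{b,d},{c,d} only {c,d} has a nonzero source (edge)
  expect_equal(nrow(sys$X), 1)
  expect_equal(sys$pairs$u, "c")
  expect_error(
    build_system(qb, g, list(k),
      node_partition("a", "b", character(0), character(0)),
      mapping = "lower"
    ),
    "fewer than 2"
  )
})

test_that("solve_weights recovers generating weights from consistent systems", {
  for (seed in 1:6) {
    su <- small_setup(25, seed = seed, n_kernels = 3)
    p <- rwr_distribution(to_transition(su$g), "v01")
    nodes <- graph_nodes(su$g)
    part <- node_partition("v01",
      near = nodes[2:10], far = nodes[20:25],
      middle = character(0)
    )
    qb <- barker_matrix(p, support = c(part$near, part$far))
    sys <- build_system(qb, su$g, su$ks, part)
    w_true <- withr::with_seed(seed, round(runif(4, 0.1, 2), 2))
    sys$rhs <- as.vector(sys$X %*% w_true)
    for (solver in c("l1_lp", "least_squares_nonneg")) {
      w <- solve_weights(sys, solver)
      got <- c(w$w0, unname(w$w))
      expect_equal(got, w_true, tolerance = 1e-6)
      expect_lt(w$residual, 1e-8)
    }
  }
})

test_that("an all-zero rhs is rejected as degenerate", {
  su <- small_setup(15, seed = 5)
  p <- rwr_distribution(to_transition(su$g), "v01")
  nodes <- graph_nodes(su$g)
  part <- node_partition("v01",
    near = nodes[2:6], far = nodes[12:15], middle = character(0)
  )
  qb <- barker_matrix(p, support = c(part$near, part$far))
  sys <- build_system(qb, su$g, su$ks, part)
  sys$rhs <- rep(0, length(sys$rhs))
  expect_error(solve_weights(sys), "all be zero")
})

test_that("weights are equivariant under kernel reordering", {
  su <- small_setup(25, seed = 7, n_kernels = 3)
  w1 <- fit_single_start(su$g, su$ks, "v01", eps1 = 2, eps2 = 3, seed = 1)
  w2 <- fit_single_start(su$g, su$ks[c(3, 1, 2)], "v01",
    eps1 = 2, eps2 = 3, seed = 1
  )
  expect_equal(w2$w[names(w1$w)], w1$w, tolerance = 1e-6)
  expect_equal(w2$w0, w1$w0, tolerance = 1e-6)
})

test_that("collinear sources still yield a usable weight vector", {
  g <- copying_model(20, seed = 9)
  adjk <- feature_kernel(as.matrix(g$adjacency), "adj_copy",
    scale = FALSE, zero_diagonal = FALSE
  )
  expect_warning(
    w <- fit_single_start(g, list(adjk, adjk), "v01", eps1 = 2, eps2 = 3),
    "collinear"
  )
  expect_s3_class(w, "wolp_weights")
  expect_true(all(c(w$w0, w$w) >= 0))
})

test_that("single-start fit runs end to end and logs its diagnostics", {
  su <- small_setup(60, seed = 11, n_kernels = 3)
  w <- fit_single_start(su$g, su$ks, "v01", eps1 = 2, eps2 = 4, seed = 3)
  fit <- attr(w, "fit")
  expect_equal(fit$start, "v01")
  expect_gt(fit$n_rows, 0)
  expect_s3_class(fit$partition, "node_partition")
  expect_false(all(c(w$w0, w$w) == 0))

  # an empty far set (eps2 beyond the diameter) must still be solvable
  w2 <- fit_single_start(su$g, su$ks, "v01", eps1 = 3, eps2 = 50, seed = 3)
  expect_equal(attr(w2, "fit")$n_far, 0)
  expect_s3_class(w2, "wolp_weights")
})

test_that("fits are deterministic for a fixed seed", {
  su <- small_setup(50, seed = 13, n_kernels = 2)
  w1 <- fit_single_start(su$g, su$ks, "v01", seed = 5)
  w2 <- fit_single_start(su$g, su$ks, "v01", seed = 5)
  expect_identical(tidy(w1), tidy(w2))
})

test_that("supervised fit with a single grid point reduces to the plain fit", {
  su <- small_setup(70, seed = 17, n_kernels = 2)
  split <- split_golden(su$g, n_validation = 8, n_test = 20, seed = 2)
  cfg <- wolp_config(
    eps1_grid = 2, eps2_grid = 4, mappings = "lower", seed = 2
  )
  fit <- fit_supervised(su$g, su$ks, split, "v01", cfg)
  train <- train_graph(split, su$g)
  direct <- fit_single_start(train, su$ks, "v01",
    eps1 = 2, eps2 = 4,
    seed = 2, max_rows = cfg$max_rows
  )
  expect_equal(tidy(fit$weights), tidy(direct))
  expect_equal(nrow(fit$grid), 1)
})

test_that("supervised fit searches the grid and breaks ties deterministically", {
  su <- small_setup(70, seed = 19, n_kernels = 2)
  split <- split_golden(su$g, n_validation = 8, n_test = 20, seed = 4)
  cfg <- wolp_config(
    eps1_grid = c(2, 3), eps2_grid = c(3, 4), mappings = c("lower", "upper"),
    seed = 4
  )
  fit <- fit_supervised(su$g, su$ks, split, "v01", cfg)
  expect_equal(nrow(fit$grid), 8) # four eps1 <= eps2 combinations x 2 mappings
  expect_equal(max(fit$grid$auc, na.rm = TRUE), fit$best$auc)
  # ties go to the first row in (eps1, eps2, lower-before-upper) order
  first_best <- which(fit$grid$auc == fit$best$auc)[1]
  expect_equal(fit$grid[first_best, ], fit$best)
  # reruns are identical
  fit2 <- fit_supervised(su$g, su$ks, split, "v01", cfg)
  expect_equal(fit$grid, fit2$grid)
})

test_that("supervised fit validates its inputs", {
  su <- small_setup(40, seed = 21)
  split <- random_edge_split(su$g, 10, seed = 1)
  expect_error(fit_supervised(su$g, su$ks, split, "v01"), "connectivity")
  sp2 <- split_golden(su$g, n_validation = 0, n_test = 10, seed = 1)
  expect_error(fit_supervised(su$g, su$ks, sp2, "v01"), "validation")
  expect_error(wolp_config(eps1_grid = numeric(0)), "empty")
  expect_error(wolp_config(eps1_grid = 5, eps2_grid = 3), "eps1")
})
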