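test_that("AUC follows the Mann-Whitney statistic on worked examples", {
  nodes <- c("a", "b", "c", "d", "e")
  pos <- tibble::tibble(from = c("a", "a"), to = c("b", "c"))
  neg <- tibble::tibble(from = c("a", "d"), to = c("d", "e"))
  m <- pair_score_matrix(
    nodes, dplyr::bind_rows(pos, neg),
    c(0.9, 0.4, 0.6, 0.1)
  )
  ev <- roc_auc(m, pos, neg)
  expect_equal(ev$auc, 0.75) # 3 of 4 pos/neg pairs correctly ordered

  perfect <- pair_score_matrix(
    nodes, dplyr::bind_rows(pos, neg), c(0.9, 0.8, 0.3, 0.1)
  )
  expect_equal(roc_auc(perfect, pos, neg)$auc, 1)

  flat <- pair_score_matrix(
    nodes, dplyr::bind_rows(pos, neg), rep(0.5, 4)
  )
  expect_equal(roc_auc(flat, pos, neg)$auc, 0.5)

  expect_error(roc_auc(m, pos[0, ], neg), "empty positive")
  expect_error(roc_auc(m, pos, neg[0, ]), "empty negative")
})

test_that("AUC agrees with a brute-force oracle on random instances", {
  for (trial in 1:50) {
    sim <- withr::with_seed(trial, {
      np <- sample(3:60, 1)
      nn <- sample(3:60, 1)
      # duplicate some scores so ties are exercised
      raw <- round(runif(np + nn), 2)
      list(pos = raw[seq_len(np)], neg = raw[np + seq_len(nn)])
    })
    n_all <- length(sim$pos) + length(sim$neg)
    nodes <- sprintf("n%03d", seq_len(n_all + 1))
    pairs <- tibble::tibble(from = nodes[1], to = nodes[-1][seq_len(n_all)])
    m <- pair_score_matrix(nodes, pairs, c(sim$pos, sim$neg))
    pos <- pairs[seq_along(sim$pos), ]
    neg <- pairs[length(sim$pos) + seq_along(sim$neg), ]
    ev <- roc_auc(m, pos, neg)
    expect_equal(ev$auc, brute_auc(sim$pos, sim$neg), tolerance = 1e-12)
  }
})

test_that("AUC matches the independent pROC implementation", {
  sim <- withr::with_seed(99, list(pos = runif(40), neg = runif(60)))
  nodes <- sprintf("n%03d", 1:101)
  pairs <- tibble::tibble(from = nodes[1], to = nodes[2:101])
  m <- pair_score_matrix(nodes, pairs, c(sim$pos, sim$neg))
  ev <- roc_auc(m, pairs[1:40, ], pairs[41:100, ])
  ref <- pROC::auc(
    response = rep(c(1, 0), c(40, 60)),
    predictor = c(sim$pos, sim$neg),
    quiet = TRUE, direction = "<"
  )
  expect_equal(ev$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("ROC points are a proper curve whose area equals the AUC", {
  for (trial in 1:10) {
    sim <- withr::with_seed(200 + trial, {
      list(pos = round(runif(30), 1), neg = round(runif(30), 1))
    })
    nodes <- sprintf("n%02d", 1:61)
    pairs <- tibble::tibble(from = nodes[1], to = nodes[2:61])
    m <- pair_score_matrix(nodes, pairs, c(sim$pos, sim$neg))
    ev <- roc_auc(m, pairs[1:30, ], pairs[31:60, ])
    expect_equal(ev$fpr[1], 0)
    expect_equal(ev$tpr[1], 0)
    expect_equal(ev$fpr[length(ev$fpr)], 1)
    expect_equal(ev$tpr[length(ev$tpr)], 1)
    expect_false(is.unsorted(ev$fpr))
    expect_false(is.unsorted(ev$tpr))
    trap <- sum(diff(ev$fpr) * (head(ev$tpr, -1) + utils::tail(ev$tpr, -1)) / 2)
    expect_equal(trap, ev$auc, tolerance = 1e-9)
  }
})

test_that("negative sampling enumerates or samples true non-edges", {
  tri <- triangle_graph()
  expect_equal(nrow(negative_sample(tri, 0, exhaustive = TRUE)), 0)

  pg <- path_graph(c("a", "b", "c"))
  expect_equal(
    negative_sample(pg, 0, exhaustive = TRUE),
    tibble::tibble(from = "a", to = "c")
  )

  g <- copying_model(60, seed = 2)
  excl <- graph_edges(g)[1:5, ] # already edges, but exercises the path
  neg <- negative_sample(g, 100, seed = 7, exclude = excl)
  expect_equal(nrow(neg), 100)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_keys <- key(graph_edges(g)$from, graph_edges(g)$to)
  expect_length(intersect(key(neg$from, neg$to), edge_keys), 0)
  expect_equal(anyDuplicated(key(neg$from, neg$to)), 0)

  expect_error(negative_sample(tri, 5), "non-edges")
})

test_that("DCG grades candidates by reference position", {
  ref <- c("x", "y", "z")
  ident <- dcg_at_k(ref, ref, k = 3)
  expect_equal(ident$dcg, 2 / log2(2) + 1 / log2(3), tolerance = 1e-10)
  expect_equal(ident$dcg, ident$ideal)

  two <- dcg_at_k(c("b", "a"), c("a", "b"), k = 2)
  expect_equal(two$dcg, 1 / log2(3), tolerance = 1e-10)

  expect_error(dcg_at_k(c("a", "b"), c("a", "c"), 2), "same set")
  expect_error(dcg_at_k(ref, ref, 4), "exceeds")
})

test_that("DCG is maximal exactly when the positive-relevance prefix leads in order", {
  # under rel = k - rank_ref the k-th reference item has relevance 0, so the
  # maximum is attained exactly when the first k - 1 reference items open the
  # candidate ranking in order
  ref <- c("a", "b", "c", "d", "e")
  k <- 3
  ideal <- dcg_at_k(ref, ref, k)$ideal
  perms <- NULL
  for (p1 in ref) for (p2 in setdiff(ref, p1)) for (p3 in setdiff(ref, c(p1, p2))) {
    rest <- setdiff(ref, c(p1, p2, p3))
    perms <- c(perms, list(c(p1, p2, p3, rest), c(p1, p2, p3, rev(rest))))
  }
  for (cand in perms) {
    d <- dcg_at_k(cand, ref, k)$dcg
    expect_lte(d, ideal + 1e-12)
    if (identical(cand[seq_len(k - 1)], ref[seq_len(k - 1)])) {
      expect_equal(d, ideal)
    } else {
      expect_lt(d, ideal)
    }
  }
})

test_that("the benchmark table compares the three inferences on one footing", {
  g <- copying_model(120, seed = 9)
  ks <- lapply(1:3, function(i) random_kernel(g, paste0("k", i), i))
  split <- split_golden(g, n_validation = 10, n_test = 40, seed = 5)
  res <- run_benchmark(g, ks, split, adjacency_only_weights(ks),
    seed = 5, stratify_distance = 3
  )
  expect_setequal(unique(res$label), c("RL_WOLP-K", "RL_G_tn", "RL_EW-K"))
  # passing the control weights as "learned" duplicates the control row
  all_stratum <- res[res$stratum == "all", ]
  expect_equal(
    all_stratum$auc[all_stratum$label == "RL_WOLP-K"],
    all_stratum$auc[all_stratum$label == "RL_G_tn"]
  )
  far <- res[res$stratum == "dist>3", ]
  expect_equal(nrow(far), 3)
  expect_true(all(far$n_pos > 0))
  expect_true(all(far$n_pos <= all_stratum$n_pos))

  res2 <- run_benchmark(g, ks, split, adjacency_only_weights(ks),
    seed = 5, stratify_distance = 3
  )
  expect_identical(as.data.frame(res), as.data.frame(res2))
})
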