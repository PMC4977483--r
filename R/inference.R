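#' Regularized Laplacian scores
#'
#' Interprets the fused matrix as edge strengths `A`, forms the Laplacian
#' `L = D - A` (with `D` the diagonal of row sums) and returns
#' `(I + alpha * L)^{-1}`, the regularized Laplacian graph kernel, whose
#' entry (i, j) is read as the interaction propensity of the pair. `alpha`
#' must lie in `(0, 1/rho(L))`, so it is specified as the fraction
#' `alpha_frac` of that bound; the spectral radius `rho(L)` is obtained by
#' power iteration (an overestimate would still keep `alpha` valid). The
#' inverse is computed via a linear solve against the identity, never by
#' cofactor inversion.
#'
#' @param fusion A `kernel_fusion`, [ppi_graph] or non-negative square
#'   matrix.
#' @param alpha_frac Fraction of the `1/rho(L)` bound, in `(0, 1)`.
#' @return A `score_matrix`: list with `scores`, `alpha`, `spectral_radius`.
#' @examples
#' g <- ppi_graph(tibble::tibble(from = "a", to = "b"))
#' regularized_laplacian(g, alpha_frac = 0.5)$scores
#' @export
regularized_laplacian <- function(fusion, alpha_frac = 0.5) {
  if (alpha_frac <= 0 || alpha_frac >= 1) abort("alpha_frac must be in (0, 1)")
  a <- if (inherits(fusion, "kernel_fusion")) {
    fusion$matrix
  } else if (inherits(fusion, "ppi_graph")) {
    as.matrix(fusion$adjacency)
  } else {
    as.matrix(fusion)
  }
  lap <- -a
  diag(lap) <- diag(lap) + rowSums(a)
  rho <- .spectral_radius(lap)
  alpha <- if (rho > 0) alpha_frac / rho else alpha_frac
  scores <- solve(diag(nrow(lap)) + alpha * lap)
  dimnames(scores) <- dimnames(a)
  structure(
    list(scores = scores, alpha = alpha, spectral_radius = rho),
    class = "score_matrix"
  )
}

# Power iteration for the dominant |eigenvalue|, rel tol 1e-6. The start
# vector must not be orthogonal-ish to the dominant eigenvector — for a
# Laplacian the constant vector is exactly the null vector — so a fixed
# pseudo-random direction is used, and a few iterations are forced before
# convergence may be declared. Any overestimate (Gershgorin fallback) still
# keeps alpha = alpha_frac / rho inside the valid range.
.spectral_radius <- function(m, tol = 1e-6, max_iter = 1000) {
  n <- nrow(m)
  if (n == 1) {
    return(abs(m[1, 1]))
  }
  v <- sin(seq_len(n)) + 0.5 # deterministic, non-degenerate direction
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- as.vector(m %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      return(0)
    }
    v <- w / nw
    lam_new <- nw
    if (i > 5 && abs(lam_new - lam) < tol * max(lam_new, 1)) {
      return(lam_new)
    }
    lam <- lam_new
  }
  # not converged: fall back to a safe upper bound (Gershgorin)
  max(rowSums(abs(m)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "<score_matrix> %dx%d (alpha %.4g, rho(L) %.4g)\n",
    nrow(x$scores), ncol(x$scores), x$alpha, x$spectral_radius
  ))
  invisible(x)
}

#' Ranked pair scores as a tibble
#'
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @return Tibble of unordered pairs `(from, to, score)` in descending
#'   score order, excluding the diagonal and any masked (training) pairs.
#' @export
tidy.score_matrix <- function(x, ...) {
  s <- x$scores
  n <- nrow(s)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  out <- tibble(
    from = rownames(s)[idx[, 1]],
    to = colnames(s)[idx[, 2]],
    score = s[idx]
  )
  mask <- attr(x, "masked")
  if (!is.null(mask) && nrow(mask) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    out <- out[!key(out$from, out$to) %in% key(mask[[1]], mask[[2]]), ]
  }
  arrange(out, desc(.data$score))
}

#' Connected-network inference
#'
#' Fuses the training network with the kernels under the given weights and
#' scores every node pair with the regularized Laplacian. Training-edge
#' pairs are recorded in the result's `"masked"` attribute: they are known
#' positives, so [tidy.score_matrix()] and the evaluation helpers keep them
#' out of the ranking.
#'
#' @param component Golden-standard [ppi_graph].
#' @param kernels List of [feature_kernel]s.
#' @param split `edge_split` with `connected_train = TRUE`.
#' @param weights A `wolp_weights` (learned, [equal_weights()] for the EW
#'   control, or [adjacency_only_weights()] for the bare-network control).
#' @param alpha_frac See [regularized_laplacian()].
#' @return A `score_matrix` with masked training pairs.
#' @export
infer_connected <- function(component, kernels, split, weights,
                            alpha_frac = 0.5) {
  if (!isTRUE(split$connected_train)) {
    abort("infer_connected needs a connectivity-preserving split")
  }
  train <- train_graph(split, component)
  sc <- regularized_laplacian(fuse(weights, train, kernels), alpha_frac)
  attr(sc, "masked") <- split$train
  sc
}

#' Disconnected-network inference
#'
#' Learns weights on a large connected component (via [fit_supervised()]),
#' then splits the edges of the full, possibly disconnected graph uniformly
#' at random, builds the fusion from the training edges plus kernels with
#' the learned weights, and scores the whole node universe with the
#' regularized Laplacian. Feature kernels bridge the components, so
#' cross-component pairs receive positive scores that the bare adjacency
#' could never produce.
#'
#' @param g The full [ppi_graph] (may be disconnected).
#' @param kernels Kernels over the full node universe.
#' @param cfg A [wolp_config()].
#' @param largest_cc Optional [ppi_graph] of the component to train on;
#'   defaults to the largest connected component of `g`.
#' @param cc_validation,cc_test Edges reserved inside the training
#'   component's golden-standard split.
#' @param test_fraction Fraction of the full edge set held out for testing.
#' @param seed Seed for both splits.
#' @return List with `weights` (a `wolp_fit`), `scores` (a `score_matrix`
#'   with the training edges masked) and `split` (the full-graph
#'   `edge_split`).
#' @export
infer_disconnected <- function(g, kernels, cfg = wolp_config(),
                               largest_cc = NULL, cc_validation = NULL,
                               cc_test = NULL, test_fraction = 0.3,
                               seed = 1) {
  if (is.null(largest_cc)) largest_cc <- largest_component(g)
  kernels_cc <- lapply(kernels, function(k) {
    feature_kernel(
      k$mat[largest_cc$node_ids, largest_cc$node_ids, drop = FALSE],
      k$name,
      scale = FALSE, zero_diagonal = FALSE
    )
  })
  m_cc <- n_edges(largest_cc)
  if (is.null(cc_validation)) cc_validation <- max(1, round(0.1 * m_cc))
  if (is.null(cc_test)) cc_test <- max(1, round(0.2 * m_cc))
  if (m_cc - cc_validation - cc_test < length(largest_cc$node_ids) - 1) {
    abort("largest component too small for a connectivity-preserving split")
  }
  cc_split <- split_golden(largest_cc, cc_validation, cc_test, seed = seed)
  hub <- top_hubs(train_graph(cc_split, largest_cc), 1)
  fit <- fit_supervised(largest_cc, kernels_cc, cc_split, hub, cfg)
  split <- random_edge_split(g, n_test = round(test_fraction * n_edges(g)), seed = seed)
  train <- train_graph(split, g)
  sc <- regularized_laplacian(
    fuse(fit$weights, train, kernels),
    cfg$alpha_frac
  )
  attr(sc, "masked") <- split$train
  list(weights = fit, scores = sc, split = split)
}

#' Largest connected component of a graph
#'
#' @param g A [ppi_graph].
#' @return A [ppi_graph] restricted to the largest component's nodes.
#' @export
largest_component <- function(g) {
  comp <- igraph::components(as_igraph(g))
  keep <- g$node_ids[comp$membership == which.max(comp$csize)]
  edges <- graph_edges(g)
  ppi_graph(edges[edges$from %in% keep & edges$to %in% keep, ], nodes = keep)
}
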