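#' Row-stochastic transition matrix
#'
#' Scales each row of a non-negative square matrix to sum to one. The kernel
#' fusion is treated as an edge-strength matrix, so stochasticity has to be
#' enforced here; all-zero rows (isolated nodes) are left zero.
#'
#' @param m Non-negative square matrix (dense or sparse), or a
#'   `kernel_fusion`.
#' @return A `transition_matrix` (a base matrix with class attribute).
#' @export
to_transition <- function(m) {
  if (inherits(m, "kernel_fusion")) m <- m$matrix
  if (inherits(m, "ppi_graph")) m <- m$adjacency
  if (any(m < 0)) abort("transition matrix requires non-negative entries")
  if (inherits(m, "Matrix")) {
    # keep sparse: scale rows through a diagonal multiply
    rs <- Matrix::rowSums(m)
    rs[rs == 0] <- 1
    q <- Matrix::Diagonal(x = 1 / rs) %*% m
    dimnames(q) <- dimnames(m)
    attr(q, "transition_matrix") <- TRUE
    return(q)
  }
  q <- row_normalize(as.matrix(m))
  class(q) <- c("transition_matrix", class(q))
  q
}

#' Random walk with restart distribution
#'
#' Iterates `p <- (1 - restart) * t(Q) %*% p + restart * e_s` from the point
#' mass at the start node until the L1 change drops below `tol`. With
#' `restart = 0` this is plain power iteration for the stationary
#' distribution of `Q`.
#'
#' @param q A `transition_matrix` (rows sum to 1 or 0).
#' @param s Start node id (must be a row name of `q`).
#' @param restart Restart probability in `[0, 1)`; default 0.15, the common
#'   random-walk-with-restart convention.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @return A `walk_distribution`: list with named probability vector `p`,
#'   `source`, `restart`, `iterations` and final `delta`.
#' @export
rwr_distribution <- function(q, s, restart = 0.15, tol = 1e-10,
                             max_iter = 10000) {
  nodes <- rownames(q)
  if (is.null(nodes)) abort("transition matrix needs node ids as dimnames")
  if (!s %in% nodes) abort(sprintf("start node '%s' not in matrix", s))
  if (restart < 0 || restart >= 1) abort("restart must be in [0, 1)")
  e_s <- as.numeric(nodes == s)
  p <- e_s
  qt <- if (inherits(q, "Matrix")) Matrix::t(q) else t(unclass(q))
  for (it in seq_len(max_iter)) {
    p_new <- as.vector((1 - restart) * (qt %*% p)) + restart * e_s
    tot <- sum(p_new)
    if (tot > 0) p_new <- p_new / tot
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      return(structure(
        list(
          p = setNames(p, nodes), source = s, restart = restart,
          iterations = it, delta = delta
        ),
        class = "walk_distribution"
      ))
    }
  }
  abort(sprintf(
    "random walk did not converge in %d iterations (last L1 change %.3g)",
    max_iter, delta
  ))
}

#' @export
print.walk_distribution <- function(x, ...) {
  cat(sprintf(
    "<walk_distribution> start=%s restart=%.2f (%d iterations)\n",
    x$source, x$restart, x$iterations
  ))
  invisible(x)
}

#' @export
tidy.walk_distribution <- function(x, ...) {
  tibble(node = names(x$p), prob = unname(x$p))
}

#' Barker transition matrix from a stationary distribution
#'
#' Builds the reversible-chain transition probabilities
#' `qb(i, j) = p_j / (p_i + p_j)` on the nodes of `support`. By
#' construction `qb(i,j) + qb(j,i) = 1` and detailed balance
#' `p_i qb(i,j) = p_j qb(j,i)` hold exactly. The diagonal is stored as 0 and
#' never consumed.
#'
#' @param p A `walk_distribution` or named probability vector.
#' @param support Node ids to include; defaults to all nodes with `p > 0`.
#' @return A `barker_matrix` (square matrix over `support`).
#' @export
barker_matrix <- function(p, support = NULL) {
  if (inherits(p, "walk_distribution")) p <- p$p
  if (is.null(names(p))) abort("p must be a named vector")
  if (is.null(support)) support <- names(p)[p > 0]
  missing <- setdiff(support, names(p))
  if (length(missing) > 0) {
    abort(sprintf("support nodes not in p: %s", paste(head(missing, 3), collapse = ", ")))
  }
  ps <- p[support]
  denom <- outer(ps, ps, "+")
  if (any(denom == 0)) {
    bad <- which(denom == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "p_i + p_j = 0 for pair (%s, %s)", support[bad[1]], support[bad[2]]
    ))
  }
  qb <- outer(rep(1, length(ps)), ps) / denom
  diag(qb) <- 0
  dimnames(qb) <- list(support, support)
  class(qb) <- c("barker_matrix", class(qb))
  qb
}
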