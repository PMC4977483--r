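#' Feature kernels
#'
#' A feature kernel is a named, symmetric, non-negative square matrix over
#' the node universe that scores pairwise similarity of proteins from one
#' data source (sequence, expression, domains, topology, ...). Kernels are
#' min-max scaled to `[0, 1]` on construction to avoid scale bias between
#' sources. The row-normalized view used in the fusion (each row divided by
#' its sum) is computed by [kernel_normalized()].
#'
#' @param mat Square numeric matrix with identical row/column names (the
#'   node ids) or no names (then `nodes` is required).
#' @param name Label for the kernel.
#' @param nodes Optional node ids for unnamed matrices.
#' @param scale Min-max scale into `[0, 1]` (default `TRUE`).
#' @param zero_diagonal Force the diagonal to zero (default `TRUE`):
#'   self-similarity is undefined for interaction prediction and a nonzero
#'   diagonal would add self-loop mass to the random walk.
#' @return A `feature_kernel`: list with `name`, `mat` and the flag
#'   `normalized` (`FALSE` until [kernel_normalized()] output is used).
#' @export
feature_kernel <- function(mat, name, nodes = NULL, scale = TRUE,
                           zero_diagonal = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("kernel matrix must be square")
  if (!is.null(nodes)) dimnames(mat) <- list(nodes, nodes)
  if (is.null(rownames(mat))) abort("kernel needs node ids (dimnames or `nodes`)")
  if (any(!is.finite(mat))) abort(sprintf("kernel '%s' has non-finite entries", name))
  if (any(mat < 0)) abort(sprintf("kernel '%s' has negative entries", name))
  if (max(abs(mat - t(mat))) > 1e-8) {
    abort(sprintf("kernel '%s' must be symmetric", name))
  }
  if (zero_diagonal) diag(mat) <- 0
  if (scale) mat <- minmax_scale(mat)
  structure(list(name = name, mat = mat, normalized = FALSE),
    class = "feature_kernel"
  )
}

#' @export
print.feature_kernel <- function(x, ...) {
  cat(sprintf(
    "<feature_kernel> '%s' %dx%d%s\n", x$name, nrow(x$mat), ncol(x$mat),
    if (x$normalized) " (row-normalized)" else ""
  ))
  invisible(x)
}

#' Min-max scale a matrix into [0, 1]
#'
#' `(x - min) / (max - min)` elementwise. A constant matrix collapses to all
#' zeros with a warning (there is no information to rescale).
#'
#' @param m Numeric matrix with finite entries.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_scale <- function(m) {
  if (any(!is.finite(m))) abort("cannot min-max scale non-finite entries")
  lo <- min(m)
  hi <- max(m)
  if (hi == lo) {
    warn("constant matrix: min-max scaling returns all zeros")
    m[] <- 0
    return(m)
  }
  (m - lo) / (hi - lo)
}

#' Row-normalize a non-negative matrix
#'
#' Divides each row by its sum; all-zero rows stay all-zero so isolated
#' nodes do not become absorbing. Output rows sum to 1 or 0.
#'
#' @param m Non-negative numeric matrix.
#' @return Matrix with row sums in \{0, 1\}.
#' @export
row_normalize <- function(m) {
  if (any(m < 0)) abort("row_normalize requires non-negative entries")
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}

#' Row-normalized view of a kernel
#'
#' @param k A [feature_kernel] (already-normalized kernels pass through).
#' @return The row-normalized kernel matrix.
#' @export
kernel_normalized <- function(k) {
  if (isTRUE(k$normalized)) k$mat else row_normalize(k$mat)
}

#' Replace a kernel's matrix with its row-normalized view
#'
#' Materializes the normalization in place of the raw matrix (useful to
#' avoid holding both views of large kernels); downstream consumers treat
#' the kernel as already normalized.
#'
#' @param k A [feature_kernel].
#' @return The kernel with `mat` row-normalized and `normalized = TRUE`.
#' @export
normalize_kernel <- function(k) {
  if (!isTRUE(k$normalized)) {
    k$mat <- row_normalize(k$mat)
    k$normalized <- TRUE
  }
  k
}

#' Topology kernels: Jaccard neighbourhood overlap and shared neighbour count
#'
#' `jaccard_kernel()` scores a pair by `|N(i) ∩ N(j)| / |N(i) ∪ N(j)|` (0
#' when the union is empty); `shared_neighbor_kernel()` by `deg(i) + deg(j)`
#' min-max scaled to `[0, 1]`. Diagonals are zero.
#'
#' @param g A [ppi_graph] (typically the training network).
#' @return A [feature_kernel].
#' @export
jaccard_kernel <- function(g) {
  a <- g$adjacency
  common <- as.matrix(a %*% a)
  deg <- Matrix::rowSums(a)
  uni <- outer(deg, deg, "+") - common
  jac <- ifelse(uni > 0, common / uni, 0)
  diag(jac) <- 0
  dimnames(jac) <- list(g$node_ids, g$node_ids)
  feature_kernel(jac, "K_Jaccard", scale = FALSE)
}

#' @rdname jaccard_kernel
#' @export
shared_neighbor_kernel <- function(g) {
  deg <- Matrix::rowSums(g$adjacency)
  sn <- outer(deg, deg, "+")
  diag(sn) <- 0
  dimnames(sn) <- list(g$node_ids, g$node_ids)
  feature_kernel(sn, "K_SN", scale = TRUE)
}

#' Fusion weight vector
#'
#' Coefficients for the weighted kernel fusion: `w0` multiplies the training
#' network adjacency and `w[i]` multiplies the i-th row-normalized kernel.
#'
#' @param w0 Non-negative coefficient for the training adjacency.
#' @param w Non-negative numeric vector, one entry per kernel.
#' @param kernel_names Optional names for `w` (defaults to existing names).
#' @param residual,solver Optional fit metadata attached by [solve_weights()].
#' @return A `wolp_weights` object.
#' @export
weight_vector <- function(w0, w, kernel_names = names(w), residual = NA_real_,
                          solver = NA_character_) {
  w <- as.numeric(w)
  if (is.null(kernel_names)) kernel_names <- paste0("K", seq_along(w))
  if (any(c(w0, w) < 0)) abort("fusion weights must be non-negative")
  if (all(c(w0, w) == 0)) abort("fusion weights cannot all be zero")
  structure(
    list(
      w0 = as.numeric(w0), w = setNames(w, kernel_names),
      residual = residual, solver = solver
    ),
    class = "wolp_weights"
  )
}

#' @export
print.wolp_weights <- function(x, ...) {
  cat(sprintf("<wolp_weights> w0=%.4g", x$w0))
  cat(sprintf(" %s=%.4g", names(x$w), x$w), sep = "")
  if (!is.na(x$residual)) cat(sprintf("  [residual %.3g]", x$residual))
  cat("\n")
  invisible(x)
}

#' Equal-weight control vector (all coefficients 1)
#'
#' @param kernels List of [feature_kernel]s the weights must align with.
#' @return A `wolp_weights` with every coefficient 1.
#' @export
equal_weights <- function(kernels) {
  weight_vector(1, rep(1, length(kernels)),
    kernel_names = vapply(kernels, `[[`, "", "name"),
    solver = "equal_weights"
  )
}

#' Training-network-only control vector (w0 = 1, kernels 0)
#'
#' @param kernels List of [feature_kernel]s the weights must align with.
#' @return A `wolp_weights` selecting only the training adjacency.
#' @export
adjacency_only_weights <- function(kernels) {
  weight_vector(1, rep(0, length(kernels)),
    kernel_names = vapply(kernels, `[[`, "", "name"),
    solver = "adjacency_only"
  )
}

#' Weighted kernel fusion
#'
#' Elementwise weighted sum of the training-network adjacency and the
#' row-normalized feature kernels:
#' `K_fusion = w0 * A(G_tn) + sum_i w_i * normalize(K_i)`.
#'
#' @param weights A `wolp_weights` (see [weight_vector()]).
#' @param train The training [ppi_graph].
#' @param kernels List of [feature_kernel]s over the same node universe.
#' @param normalization `"row"` (default) divides kernel rows by their sums;
#'   `"symmetric"` uses `K(u,v)/sqrt(d_u d_v)`, which preserves symmetry;
#'   `"none"` fuses the raw symmetric `[0, 1]` kernels directly (the form
#'   the synthetic rank-agreement experiment uses, where the fused matrix
#'   must stay symmetric).
#' @return A `kernel_fusion`: list with the fused `matrix`, the `weights`
#'   used and the `components` names.
#' @export
fuse <- function(weights, train, kernels,
                 normalization = c("row", "symmetric", "none")) {
  normalization <- match.arg(normalization)
  if (length(weights$w) != length(kernels)) {
    abort("weight count must equal kernel count (plus w0 for the adjacency)")
  }
  n <- length(train$node_ids)
  fusion <- weights$w0 * as.matrix(train$adjacency)
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    if (!all(dim(k$mat) == n)) abort("kernel dimensions must match the graph")
    if (weights$w[i] == 0) next
    kn <- switch(normalization,
      row = kernel_normalized(k),
      symmetric = .sym_normalize(k$mat),
      none = k$mat
    )
    fusion <- fusion + weights$w[i] * kn
  }
  dimnames(fusion) <- list(train$node_ids, train$node_ids)
  structure(
    list(
      matrix = fusion, weights = weights,
      components = c("G_tn", vapply(kernels, `[[`, "", "name"))
    ),
    class = "kernel_fusion"
  )
}

.sym_normalize <- function(m) {
  d <- sqrt(rowSums(m))
  d[d == 0] <- 1
  m / outer(d, d)
}

#' @export
print.kernel_fusion <- function(x, ...) {
  cat(sprintf(
    "<kernel_fusion> %dx%d from %s\n", nrow(x$matrix), ncol(x$matrix),
    paste(x$components, collapse = " + ")
  ))
  invisible(x)
}

#' @export
tidy.wolp_weights <- function(x, ...) {
  tibble(
    component = c("G_tn", names(x$w)),
    weight = c(x$w0, unname(x$w))
  )
}

#' @export
glance.wolp_weights <- function(x, ...) {
  tibble(
    n_kernels = length(x$w), residual = x$residual, solver = x$solver
  )
}

#' @export
autoplot.wolp_weights <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$component, -.data$weight),
    y = .data$weight
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fusion weight")
}
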