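#' Assemble the weight-fitting constraint system
#'
#' One linear constraint per qualifying node pair \{u, v\} from the near/far
#' training sets D and L:
#' `w0 * A(u,v) + sum_i w_i * K_i(u,v) = qb(u,v)`,
#' where `A` is the training adjacency, `K_i` are the row-normalized feature
#' kernels and `qb` the Barker transition matrix. Because `qb` is asymmetric
#' while the fusion is built from one triangle, either the lower-triangle
#' orientation (`u < v` in node-index order) or the upper one (`u > v`) is
#' used. A pair qualifies when at least one coefficient is nonzero (or, with
#' `require_all_nonzero = TRUE`, when every kernel coefficient is nonzero).
#' Rows are ordered by node-index pair for determinism.
#'
#' @param qb A `barker_matrix` covering the partition's D and L nodes.
#' @param train Training [ppi_graph].
#' @param kernels List of [feature_kernel]s.
#' @param part A `node_partition` (see [partition_nodes()]).
#' @param mapping `"lower"` or `"upper"` triangle orientation.
#' @param require_all_nonzero Keep a pair only if every kernel speaks to it.
#' @param coefficients `"normalized"` (default) fills the kernel columns
#'   with the row-normalized view that the fusion uses;
#'   `"raw"` uses the raw symmetric `[0, 1]` kernel values, keeping the
#'   coefficient scale commensurate with the Barker probabilities on the
#'   right-hand side.
#' @param signal_threshold Optional per-kernel vector (or single value):
#'   kernel entries at or below it count as "no feature" — they are zeroed
#'   in the coefficient columns and cannot qualify a pair. `NULL` keeps
#'   every nonzero entry (the right choice for sparse kernels, whose
#'   background is exactly zero).
#' @return A `wolp_system`: list with design matrix `X` (columns `G_tn`,
#'   kernel names), right-hand side `rhs`, the `pairs` tibble, `mapping` and
#'   `partition`.
#' @export
build_system <- function(qb, train, kernels, part,
                         mapping = c("lower", "upper"),
                         require_all_nonzero = FALSE,
                         coefficients = c("normalized", "raw"),
                         signal_threshold = NULL) {
  mapping <- match.arg(mapping)
  coefficients <- match.arg(coefficients)
  nodes <- train$node_ids
  dl <- intersect(nodes, c(part$near, part$far)) # node-index (lexicographic) order
  if (length(dl) < 2) abort("no training constraints: D ∪ L has fewer than 2 nodes")
  if (!all(dl %in% rownames(qb))) abort("`qb` must cover all D ∪ L nodes")
  idx <- utils::combn(length(dl), 2)
  a <- dl[idx[1, ]] # lower node index
  b <- dl[idx[2, ]]
  if (mapping == "lower") {
    u <- a
    v <- b
  } else {
    u <- b
    v <- a
  }
  kn <- lapply(kernels, function(k) {
    if (coefficients == "raw") {
      k$mat[dl, dl, drop = FALSE]
    } else {
      kernel_normalized(k)[dl, dl, drop = FALSE]
    }
  })
  ui <- match(u, dl)
  vi <- match(v, dl)
  asub <- as.matrix(train$adjacency[dl, dl, drop = FALSE])
  X <- cbind(
    asub[cbind(ui, vi)],
    do.call(cbind, lapply(kn, function(m) m[cbind(ui, vi)]))
  )
  if (!is.null(signal_threshold)) {
    thr <- rep_len(signal_threshold, length(kernels))
    for (i in seq_along(kernels)) {
      col <- X[, i + 1]
      col[col <= thr[i]] <- 0
      X[, i + 1] <- col
    }
  }
  knames <- vapply(kernels, `[[`, "", "name")
  colnames(X) <- c("G_tn", knames)
  rhs <- qb[dl, dl][cbind(ui, vi)]
  keep <- if (require_all_nonzero) {
    rowSums(X[, -1, drop = FALSE] != 0) == length(kernels)
  } else {
    rowSums(X != 0) > 0
  }
  X <- X[keep, , drop = FALSE]
  rhs <- rhs[keep]
  if (nrow(X) == 0) abort("no training constraints: all candidate pairs have zero coefficients")
  if (nrow(X) < ncol(X)) {
    warn(sprintf(
      "constraint system is no longer overdetermined (%d rows < %d unknowns)",
      nrow(X), ncol(X)
    ))
  }
  structure(
    list(
      X = X, rhs = as.numeric(rhs),
      pairs = tibble(u = u[keep], v = v[keep]),
      mapping = mapping, partition = part
    ),
    class = "wolp_system"
  )
}

#' @export
print.wolp_system <- function(x, ...) {
  cat(sprintf(
    "<wolp_system> %d constraints, %d unknowns (%s mapping)\n",
    nrow(x$X), ncol(x$X), x$mapping
  ))
  invisible(x)
}

#' Solve for fusion weights
#'
#' Fits non-negative weights to the overdetermined constraint system. The
#' `"l1_lp"` solver minimizes the summed absolute residual as a linear
#' program (interior point, with a minimum-norm tie-break among optima);
#' `"least_squares_nonneg"` minimizes the squared residual with
#' `pracma::lsqnonneg`. Both are deterministic.
#'
#' @param sys A `wolp_system` from [build_system()].
#' @param solver `"l1_lp"` (default) or `"least_squares_nonneg"`.
#' @return A `wolp_weights` with the achieved residual (summed absolute
#'   residual for `"l1_lp"`, summed squared residual for the least-squares
#'   solver) and the solver name in its metadata.
#' @export
solve_weights <- function(sys, solver = c("l1_lp", "least_squares_nonneg")) {
  solver <- match.arg(solver)
  X <- sys$X
  rhs <- sys$rhs
  if (qr(X)$rank < ncol(X)) {
    warn("collinear constraint columns: weights are not uniquely determined")
  }
  if (solver == "l1_lp") {
    fit <- l1_linprog(X, rhs)
    w <- fit$w
    residual <- fit$objective
  } else {
    fit <- pracma::lsqnonneg(X, rhs)
    w <- fit$x
    residual <- sum((as.vector(X %*% w) - rhs)^2)
  }
  weight_vector(
    w0 = w[1], w = w[-1], kernel_names = colnames(X)[-1],
    residual = residual, solver = solver
  )
}

#' End-to-end weight fitting from one start node
#'
#' Runs the full single-start pipeline on a training network: random walk
#' with restart from `s`, Barker right-hand sides on the near/far node sets
#' D and L, constraint assembly on the chosen triangle, and the LP (or
#' NNLS) solve.
#'
#' Constraint rows are drawn from the signal support within D \eqn{\cup} L:
#' pairs carrying a training-network edge or an above-background entry in
#' some kernel. Per-kernel background thresholds are `median + 3 * MAD` of
#' the kernel's entries — for a sparse kernel (background exactly zero) this
#' degenerates to "any nonzero entry", the usual support rule; for kernels
#' with a dense noise floor it keeps the pairs the data actually speak to,
#' and entries at or below the floor count as "no feature" (coefficient 0).
#' The system is vastly overdetermined, so when the support exceeds
#' `max_rows` a seeded uniform subsample of rows is used.
#'
#' D and L play the role of positive and negative training examples, and on
#' scale-free networks the far set can outnumber the near set by two orders
#' of magnitude; the far set is therefore undersampled (seeded) to at most
#' `far_ratio` times the near set before rows are built — the usual
#' majority-class undersampling.
#'
#' @param train Training [ppi_graph].
#' @param kernels List of [feature_kernel]s.
#' @param s Start node id (typically a hub).
#' @param eps1,eps2 Hop thresholds for the D/L partition.
#' @param mapping Triangle orientation, `"lower"` or `"upper"`.
#' @param restart Restart probability of the walk.
#' @param solver Weight solver (see [solve_weights()]).
#' @param max_rows Cap on the number of constraint rows.
#' @param far_ratio Cap on |L| as a multiple of |D| (majority-class
#'   undersampling); `Inf` disables it.
#' @param seed Seed for the subsampling steps.
#' @param coefficients Kernel coefficient scale for the constraint rows:
#'   `"raw"` (default) keeps kernels on their `[0, 1]` similarity scale,
#'   commensurate with the Barker probabilities on the right-hand side;
#'   `"normalized"` uses the row-normalized view.
#' @return A `wolp_weights`; attribute `"fit"` records sizes, the partition
#'   and the achieved residual.
#' @export
fit_single_start <- function(train, kernels, s, eps1 = 2, eps2 = 4,
                             mapping = c("lower", "upper"), restart = 0.15,
                             solver = c("l1_lp", "least_squares_nonneg"),
                             max_rows = 1200, far_ratio = 2, seed = 1,
                             coefficients = c("raw", "normalized")) {
  mapping <- match.arg(mapping)
  solver <- match.arg(solver)
  coefficients <- match.arg(coefficients)
  part <- partition_nodes(train, s, eps1, eps2)
  part_fit <- .balance_far_set(part, far_ratio, seed)
  p <- rwr_distribution(to_transition(train), s, restart = restart)
  sys <- .signal_system(
    p, train, kernels,
    part_edges = part, part_kernels = part_fit,
    mapping = mapping, coefficients = coefficients,
    thresholds = signal_thresholds(kernels), max_rows = max_rows, seed = seed
  )
  w <- solve_weights(sys, solver)
  attr(w, "fit") <- list(
    start = s, n_near = length(part_fit$near), n_far = length(part_fit$far),
    n_rows = nrow(sys$X), residual = w$residual, mapping = mapping,
    restart = restart, coefficients = coefficients, partition = part
  )
  w
}

# undersample the far (negative) class to at most far_ratio * |near|
.balance_far_set <- function(part, far_ratio, seed) {
  cap <- ceiling(far_ratio * max(length(part$near), 1))
  if (!is.finite(cap) || length(part$far) <= cap) {
    return(part)
  }
  far <- withr::with_seed(seed, sort(sample(part$far, cap)))
  node_partition(part$source, part$near, far, part$middle,
    eps1 = part$eps1, eps2 = part$eps2
  )
}

#' Per-kernel background ("no feature") thresholds
#'
#' `median + 3 * MAD` of each kernel's entries, computed on a deterministic
#' stride sample for large matrices. Sparse kernels get a threshold of 0,
#' i.e. every nonzero entry counts as signal.
#'
#' @param kernels List of [feature_kernel]s.
#' @return Numeric vector of thresholds, one per kernel.
#' @export
signal_thresholds <- function(kernels) {
  vapply(kernels, function(k) {
    v <- k$mat
    len <- length(v)
    if (len > 2e5) v <- v[seq(1, len, by = max(1L, len %/% 200000L))]
    stats::median(v) + 3 * stats::mad(v)
  }, 0)
}

# Constraint system on the signal support: training-network edges within the
# full D ∪ L plus above-threshold kernel entries within the class-balanced
# D ∪ L, with Barker right-hand sides computed directly from the walk
# distribution (Barker construction applied directly). Edge rows are never balanced away — the
# training network is the backbone source and its rows anchor w0 — while
# kernel rows come from the balanced sets so the far-far background cannot
# swamp the system. Returns the same `wolp_system` structure as
# build_system().
.signal_system <- function(p, train, kernels, part_edges, part_kernels,
                           mapping, coefficients, thresholds, max_rows, seed) {
  nodes <- train$node_ids
  n <- length(nodes)
  in_dl_e <- rep(FALSE, n)
  in_dl_e[match(c(part_edges$near, part_edges$far), nodes)] <- TRUE
  in_dl_k <- rep(FALSE, n)
  in_dl_k[match(c(part_kernels$near, part_kernels$far), nodes)] <- TRUE
  if (sum(in_dl_e) < 2) abort("no training constraints: D ∪ L has fewer than 2 nodes")
  eidx <- Matrix::which(Matrix::triu(train$adjacency, 1) != 0, arr.ind = TRUE)
  keep <- in_dl_e[eidx[, 1]] & in_dl_e[eidx[, 2]]
  ci <- eidx[keep, 1]
  cj <- eidx[keep, 2]
  for (ii in seq_along(kernels)) {
    idx <- which(kernels[[ii]]$mat > thresholds[ii])
    i0 <- (idx - 1L) %% n + 1L
    j0 <- (idx - 1L) %/% n + 1L
    keep <- i0 < j0 & in_dl_k[i0] & in_dl_k[j0]
    ci <- c(ci, i0[keep])
    cj <- c(cj, j0[keep])
  }
  if (length(ci) == 0) {
    abort("no training constraints: no edge or kernel signal within D ∪ L")
  }
  key <- as.numeric(ci) * (n + 1) + cj
  ord <- order(key)
  ci <- ci[ord]
  cj <- cj[ord]
  dup <- duplicated(key[ord])
  ci <- ci[!dup]
  cj <- cj[!dup]
  if (length(ci) > max_rows) {
    pick <- sort(withr::with_seed(seed, sample.int(length(ci), max_rows)))
    ci <- ci[pick]
    cj <- cj[pick]
  }
  if (mapping == "lower") {
    ui <- ci
    vi <- cj
  } else {
    ui <- cj
    vi <- ci
  }
  pv <- p$p[nodes]
  rhs <- pv[vi] / (pv[ui] + pv[vi])
  if (any(!is.finite(rhs))) {
    abort("walk probabilities vanish on some constrained pair (p_i + p_j = 0)")
  }
  cols <- lapply(seq_along(kernels), function(ii) {
    val <- kernels[[ii]]$mat[cbind(ui, vi)]
    if (coefficients == "normalized" && !isTRUE(kernels[[ii]]$normalized)) {
      rs <- rowSums(kernels[[ii]]$mat)
      rs[rs == 0] <- 1
      val <- val / rs[ui]
    }
    val[kernels[[ii]]$mat[cbind(ui, vi)] <= thresholds[ii]] <- 0
    val
  })
  X <- cbind(train$adjacency[cbind(ui, vi)], do.call(cbind, cols))
  colnames(X) <- c("G_tn", vapply(kernels, `[[`, "", "name"))
  structure(
    list(
      X = X, rhs = as.numeric(rhs),
      pairs = tibble(u = nodes[ui], v = nodes[vi]),
      mapping = mapping, partition = part_edges
    ),
    class = "wolp_system"
  )
}

#' Hyperparameter configuration for supervised weight learning
#'
#' @param eps1_grid,eps2_grid Candidate hop thresholds (pairs with
#'   `eps1 <= eps2` are searched).
#' @param mappings Triangle orientations to try.
#' @param restart Restart probability of the training walk.
#' @param solver Weight solver.
#' @param alpha_frac Regularized-Laplacian `alpha` as a fraction of
#'   `1/rho(L)`.
#' @param neg_ratio Validation negatives sampled per positive.
#' @param max_rows Cap on constraint rows (see [fit_single_start()]).
#' @param seed Integer seed for sampling steps.
#' @return A `wolp_config` list.
#' @export
wolp_config <- function(eps1_grid = c(2, 3), eps2_grid = c(3, 4, 5),
                        mappings = c("lower", "upper"), restart = 0.15,
                        solver = c("l1_lp", "least_squares_nonneg"),
                        alpha_frac = 0.5, neg_ratio = 10,
                        max_rows = 1200, seed = 1) {
  solver <- match.arg(solver)
  if (length(eps1_grid) == 0 || length(eps2_grid) == 0) abort("empty eps grid")
  feasible <- any(outer(eps1_grid, eps2_grid, "<="))
  if (!feasible) abort("no eps1 <= eps2 combination in the grids")
  structure(
    list(
      eps1_grid = eps1_grid, eps2_grid = eps2_grid, mappings = mappings,
      restart = restart, solver = solver, alpha_frac = alpha_frac,
      neg_ratio = neg_ratio, max_rows = max_rows, seed = seed
    ),
    class = "wolp_config"
  )
}

#' Supervised weight learning with validation-AUC model selection
#'
#' Grid-searches the D/L hop thresholds and the triangle orientation: for
#' each setting the single-start fit is run on the training network, the
#' fused kernel is scored with the regularized Laplacian, and the AUC of
#' recovering the validation edges (against sampled non-edges of the full
#' component) is recorded. The weights with the best validation AUC win;
#' ties break to the smaller `(eps1, eps2)` and lower-before-upper mapping.
#'
#' @param component The golden-standard [ppi_graph] (a connected component).
#' @param kernels List of [feature_kernel]s.
#' @param split An `edge_split` with `connected_train = TRUE` and a
#'   non-empty validation set.
#' @param s Start node id in the training network.
#' @param cfg A [wolp_config()].
#' @return A `wolp_fit`: list with the winning `weights`, the full `grid`
#'   tibble (one row per setting, with validation AUC), `best` (the winning
#'   row), `start` and `config`.
#' @export
fit_supervised <- function(component, kernels, split, s, cfg = wolp_config()) {
  if (!isTRUE(split$connected_train)) {
    abort("fit_supervised needs a connectivity-preserving split (split_golden)")
  }
  if (nrow(split$validation) == 0) abort("validation edge set is empty")
  train <- train_graph(split, component)
  pos <- split$validation
  neg <- negative_sample(
    component,
    n = min(cfg$neg_ratio * nrow(pos), .n_nonedges(component)),
    seed = cfg$seed
  )
  grid <- expand.grid(
    eps1 = cfg$eps1_grid, eps2 = cfg$eps2_grid,
    mapping = cfg$mappings, stringsAsFactors = FALSE
  )
  grid <- grid[grid$eps1 <= grid$eps2, , drop = FALSE]
  grid <- grid[order(grid$eps1, grid$eps2, match(grid$mapping, c("lower", "upper"))), ]
  if (nrow(grid) == 0) abort("empty hyperparameter grid")
  fits <- vector("list", nrow(grid))
  auc <- rep(NA_real_, nrow(grid))
  errors <- character(0)
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(
      {
        w <- fit_single_start(
          train, kernels, s,
          eps1 = grid$eps1[i], eps2 = grid$eps2[i], mapping = grid$mapping[i],
          restart = cfg$restart, solver = cfg$solver,
          max_rows = cfg$max_rows, seed = cfg$seed
        )
        sc <- regularized_laplacian(fuse(w, train, kernels), cfg$alpha_frac)
        list(w = w, auc = roc_auc(sc, pos, neg)$auc)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf(
        "eps1=%s eps2=%s %s: %s",
        grid$eps1[i], grid$eps2[i], grid$mapping[i], conditionMessage(res)
      ))
    } else {
      fits[[i]] <- res$w
      auc[i] <- res$auc
    }
  }
  if (all(is.na(auc))) {
    abort(paste(
      c("every grid point failed:", errors),
      collapse = "\n  "
    ))
  }
  best_i <- which.max(auc) # grid is pre-sorted, so ties go to the first
  grid_tb <- as_tibble(grid)
  grid_tb$auc <- auc
  structure(
    list(
      weights = fits[[best_i]], grid = grid_tb,
      best = grid_tb[best_i, , drop = FALSE], start = s, config = cfg
    ),
    class = "wolp_fit"
  )
}

#' @export
print.wolp_fit <- function(x, ...) {
  cat(sprintf(
    "<wolp_fit> start=%s best: eps1=%s eps2=%s %s (validation AUC %.4f)\n",
    x$start, x$best$eps1, x$best$eps2, x$best$mapping, x$best$auc
  ))
  print(x$weights)
  invisible(x)
}

#' @export
tidy.wolp_fit <- function(x, ...) tidy(x$weights)

#' @export
glance.wolp_fit <- function(x, ...) {
  tibble(
    start = x$start, eps1 = x$best$eps1, eps2 = x$best$eps2,
    mapping = x$best$mapping, validation_auc = x$best$auc,
    residual = x$weights$residual, solver = x$weights$solver
  )
}

#' @export
autoplot.wolp_fit <- function(object, ...) autoplot(object$weights, ...)
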