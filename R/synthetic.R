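#' Synthetic benchmark specification
#'
#' Parameters of the synthetic study conditions: a copying-model scale-free
#' network plus eight feature kernels split into three categories — noise
#' kernels (background plus a boosted mask over non-edges), positive kernels
#' (background plus a boosted mask over true edges) and one mixture kernel
#' (both masks). Each kernel's mask density `rho_i` is drawn once, uniformly
#' from `[0.2, 0.6]`, at construction, so the sampled values travel with the
#' spec into run manifests.
#'
#' @param n_nodes Number of nodes (default 5093, matching the scale and
#'   density of the DIP yeast network the benchmark emulates).
#' @param copy_prob Probability of uniform partner selection in the copying
#'   model (default 0.8; otherwise degree-proportional).
#' @param eta Signal offset added to masked entries, in `[0, 1]`
#'   (default 0.5).
#' @param densities Optional vector of per-kernel mask densities `rho_i`
#'   (fractions of the edge count); drawn from `[0.2, 0.6]` when `NULL`.
#' @param kernel_plan Named counts per category; default
#'   `c(noise = 3, positive = 4, mixture = 1)`.
#' @param seed Integer seed driving the network, densities and kernels.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 5093, copy_prob = 0.8, eta = 0.5,
                           densities = NULL,
                           kernel_plan = c(noise = 3, positive = 4, mixture = 1),
                           seed = 1) {
  if (n_nodes < 3) abort("n_nodes must be at least 3")
  if (copy_prob < 0 || copy_prob > 1) abort("copy_prob must be in [0, 1]")
  if (eta < 0 || eta > 1) abort("eta must be in [0, 1]")
  if (!all(c("noise", "positive", "mixture") %in% names(kernel_plan))) {
    abort("kernel_plan needs counts for noise, positive and mixture")
  }
  total <- sum(kernel_plan)
  if (is.null(densities)) {
    densities <- withr::with_seed(seed, runif(total, 0.2, 0.6))
  }
  if (length(densities) != total) {
    abort("densities must have one entry per kernel")
  }
  if (any(densities <= 0) || any(densities > 1)) {
    abort("densities must lie in (0, 1]")
  }
  structure(
    list(
      n_nodes = n_nodes, copy_prob = copy_prob, eta = eta,
      densities = densities, kernel_plan = kernel_plan, seed = seed
    ),
    class = "synthetic_spec"
  )
}

#' Copying-model scale-free network
#'
#' Starts from a triangle of three founder nodes and adds the remaining
#' nodes one at a time, each with exactly two edges to distinct existing
#' nodes. Each partner is chosen uniformly at random with probability
#' `copy_prob` and proportionally to current degree otherwise; duplicate
#' partners are redrawn. The final edge count is exactly `3 + 2 (n - 3)`.
#' Node ids are zero-padded in insertion order, so the lexicographic node
#' ordering coincides with age and the founders are the first three ids.
#'
#' @param n Number of nodes (at least 3).
#' @param copy_prob Probability of the uniform selection mechanism.
#' @param seed Integer seed.
#' @return A [ppi_graph].
#' @export
copying_model <- function(n, copy_prob = 0.8, seed = 1) {
  if (n < 3) abort("copying model needs at least 3 nodes")
  width <- nchar(as.character(n))
  ids <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  from <- integer(3 + 2 * max(n - 3, 0))
  to <- integer(length(from))
  from[1:3] <- c(1L, 2L, 1L)
  to[1:3] <- c(2L, 3L, 3L)
  deg <- integer(n)
  deg[1:3] <- 2L
  e <- 3L
  withr::with_seed(seed, {
    for (u in seq_len(n)[-(1:3)]) {
      existing <- u - 1L
      partners <- integer(0)
      while (length(partners) < 2) {
        v <- if (runif(1) < copy_prob) {
          sample.int(existing, 1)
        } else {
          sample.int(existing, 1, prob = deg[seq_len(existing)])
        }
        if (!v %in% partners) partners <- c(partners, v)
      }
      from[e + 1:2] <- u
      to[e + 1:2] <- partners
      deg[u] <- 2L
      deg[partners] <- deg[partners] + 1L
      e <- e + 2L
    }
  })
  ppi_graph(tibble(from = ids[from], to = ids[to]), nodes = ids)
}

#' Founder nodes of a copying-model graph
#'
#' @param g A [ppi_graph] from [copying_model()].
#' @return The three oldest node ids (the seed triangle).
#' @export
founder_nodes <- function(g) head(g$node_ids, 3)

#' Random edge-subnetwork mask
#'
#' Symmetric 0/1 matrix holding `round(rho * |E|)` edges sampled uniformly
#' without replacement from the edges of `g`. Density is read as a fraction
#' of the graph's edge count so positive and noise masks carry comparable
#' mass.
#'
#' @param g A [ppi_graph].
#' @param rho Fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return Sparse symmetric 0/1 matrix over the node universe.
#' @export
rand_sub <- function(g, rho, seed) {
  if (rho <= 0 || rho > 1) abort("rho must be in (0, 1]")
  edges <- graph_edges(g)
  m <- round(rho * nrow(edges))
  pick <- withr::with_seed(seed, sample.int(nrow(edges), m))
  .pair_mask(g, edges[pick, , drop = FALSE])
}

#' Random non-edge (difference) mask
#'
#' Symmetric 0/1 matrix holding `round(rho * |E|)` node pairs sampled
#' uniformly from the non-edges of `g` (pairs that are 1 in the all-ones
#' matrix but 0 in the adjacency); the mask is zero wherever `g` has an
#' edge.
#'
#' @inheritParams rand_sub
#' @return Sparse symmetric 0/1 matrix with no entry on an edge of `g`.
#' @export
rand_diff <- function(g, rho, seed) {
  if (rho <= 0 || rho > 1) abort("rho must be in (0, 1]")
  n <- length(g$node_ids)
  n_edges_g <- n_edges(g)
  m <- round(rho * n_edges_g)
  avail <- n * (n - 1) / 2 - n_edges_g
  if (avail < m) {
    abort(sprintf("only %d non-edges available, %d requested", avail, m))
  }
  pairs <- withr::with_seed(seed, .sample_nonedges(g, m, exclude_key = NULL))
  .pair_mask(g, pairs)
}

# uniform sample of m non-edge pairs (i < j), optionally excluding extra keys;
# assumes the RNG is already seeded by the caller
.sample_nonedges <- function(g, m, exclude_key = NULL) {
  n <- length(g$node_ids)
  adj <- g$adjacency
  if (n <= 400) {
    full <- which(upper.tri(matrix(0, n, n)) & as.matrix(adj) == 0, arr.ind = TRUE)
    key <- paste(full[, 1], full[, 2])
    if (!is.null(exclude_key)) {
      keep <- !key %in% exclude_key
      full <- full[keep, , drop = FALSE]
    }
    if (nrow(full) < m) abort("not enough non-edges to sample")
    pick <- full[sample.int(nrow(full), m), , drop = FALSE]
    return(tibble(from = g$node_ids[pick[, 1]], to = g$node_ids[pick[, 2]]))
  }
  got_i <- integer(0)
  got_j <- integer(0)
  seen <- character(0)
  guard <- 0
  while (length(got_i) < m) {
    guard <- guard + 1
    if (guard > 200) abort("non-edge sampling failed to find enough pairs")
    need <- m - length(got_i)
    i <- sample.int(n, 2 * need + 10, replace = TRUE)
    j <- sample.int(n, 2 * need + 10, replace = TRUE)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    ok <- lo != hi & adj[cbind(lo, hi)] == 0
    key <- paste(lo, hi)
    ok <- ok & !duplicated(key) & !key %in% seen
    if (!is.null(exclude_key)) ok <- ok & !key %in% exclude_key
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    got_i <- c(got_i, lo[take])
    got_j <- c(got_j, hi[take])
    seen <- c(seen, key[take])
  }
  tibble(from = g$node_ids[got_i], to = g$node_ids[got_j])
}

.pair_mask <- function(g, pairs) {
  n <- length(g$node_ids)
  i <- match(pairs[[1]], g$node_ids)
  j <- match(pairs[[2]], g$node_ids)
  sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
    dimnames = list(g$node_ids, g$node_ids)
  )
}

#' Build the synthetic feature kernels
#'
#' For each kernel a fresh uniform `[0, 1]` background matrix `R` is drawn
#' and symmetrized as `(R + t(R)) / 2`; masked entries then receive an extra
#' `R + eta`. Noise kernels use a non-edge mask, positive kernels an edge
#' mask, the mixture kernel both (sharing its `rho_i`). All kernels are
#' min-max scaled to `[0, 1]` unless `scale = FALSE` (useful to inspect the
#' raw offset algebra).
#'
#' @param g The [ppi_graph] the kernels annotate.
#' @param spec A [synthetic_spec()].
#' @param scale Min-max scale the kernels (default `TRUE`).
#' @return List of [feature_kernel]s named `noise1..`, `positive1..`,
#'   `mixture1`, with per-kernel `rho` and category attached as attributes.
#' @export
make_kernels <- function(g, spec, scale = TRUE) {
  n <- length(g$node_ids)
  plan <- rep(names(spec$kernel_plan), spec$kernel_plan)
  counts <- stats::ave(seq_along(plan), plan, FUN = seq_along)
  out <- vector("list", length(plan))
  for (jj in seq_along(plan)) {
    kind <- plan[jj]
    rho <- spec$densities[jj]
    kseed <- spec$seed + 101L * jj
    bg <- withr::with_seed(kseed, matrix(runif(n * n), n, n))
    bg <- (bg + t(bg)) / 2
    mat <- bg
    if (kind %in% c("positive", "mixture")) {
      idx <- Matrix::which(rand_sub(g, rho, seed = kseed + 51L) != 0)
      mat[idx] <- mat[idx] + bg[idx] + spec$eta
    }
    if (kind %in% c("noise", "mixture")) {
      idx <- Matrix::which(rand_diff(g, rho, seed = kseed + 52L) != 0)
      mat[idx] <- mat[idx] + bg[idx] + spec$eta
    }
    dimnames(mat) <- list(g$node_ids, g$node_ids)
    fk <- feature_kernel(
      mat, sprintf("%s%d", kind, counts[jj]),
      scale = scale, zero_diagonal = TRUE
    )
    attr(fk, "category") <- kind
    attr(fk, "rho") <- rho
    out[[jj]] <- fk
  }
  out
}

#' Synthetic rank-agreement benchmark (optimized vs equal-weight fusion)
#'
#' Reproduces the single-start synthetic experiment: one copying-model
#' network is generated, and for each repetition the eight kernels are
#' rebuilt, a founder node is taken as start, the nodes are partitioned
#' into D/L (training) and M (held out), weights are fitted by the Barker +
#' LP pipeline, and three random-walk distributions are computed — `p` on
#' the optimized fusion, `p''` on the equal-weight fusion and the reference
#' `p'` on the network itself. The repetition's score pair is
#' `DCG@k(p(M), p'(M))` vs `DCG@k(p''(M), p'(M))`; the optimized fusion
#' "wins" when its DCG is larger, i.e. its ranking of the held-out nodes
#' agrees better with the network's own walk.
#'
#' @param spec A [synthetic_spec()].
#' @param repetitions Number of repetitions (default 10).
#' @param k DCG rank depth (default 20).
#' @param eps1,eps2 Hop thresholds of the D/L partition.
#' @param mapping Triangle orientation for the constraint system.
#' @param restart Restart probability for all three walks.
#' @param solver Weight solver.
#' @param max_rows Cap on constraint rows (see [fit_single_start()]).
#' @param verbose Print one progress line per repetition.
#' @return Tibble with one row per repetition: `repetition`, `start`,
#'   `dcg_opt`, `dcg_ew`, `win`; attribute `"manifest"` records every
#'   sampled parameter.
#' @export
rank_agreement_experiment <- function(spec, repetitions = 10, k = 20, eps1 = 2,
                              eps2 = 4, mapping = "lower", restart = 0.15,
                              solver = "l1_lp", max_rows = 1200,
                              verbose = FALSE) {
  if (repetitions < 1) abort("repetitions must be at least 1")
  g <- copying_model(spec$n_nodes, spec$copy_prob, seed = spec$seed)
  founders <- founder_nodes(g)
  q_syn <- to_transition(g)
  rows <- vector("list", repetitions)
  manifests <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    start <- founders[(r - 1) %% 3 + 1]
    spec_r <- synthetic_spec(
      n_nodes = spec$n_nodes, copy_prob = spec$copy_prob, eta = spec$eta,
      kernel_plan = spec$kernel_plan, seed = spec$seed + 1009L * r
    )
    ks <- make_kernels(g, spec_r)
    w <- fit_single_start(
      g, ks, start,
      eps1 = eps1, eps2 = eps2, mapping = mapping, restart = restart,
      solver = solver, max_rows = max_rows, seed = spec_r$seed,
      coefficients = "raw"
    )
    part <- attr(w, "fit")$partition
    m_set <- part$middle
    # the fit used the raw kernels; the fusions use the row-normalized view,
    # so materialize it in place once rather than twice (one per fusion)
    for (i in seq_along(ks)) ks[[i]] <- normalize_kernel(ks[[i]])
    if (length(m_set) < k) {
      abort(sprintf("held-out set M has %d < k = %d nodes", length(m_set), k))
    }
    p_ref <- rwr_distribution(q_syn, start, restart = restart)
    p_opt <- rwr_distribution(
      to_transition(fuse(w, g, ks)), start,
      restart = restart
    )
    p_ew <- rwr_distribution(
      to_transition(fuse(equal_weights(ks), g, ks)), start,
      restart = restart
    )
    rank_of <- function(p) m_set[order(-p$p[m_set], m_set, method = "radix")]
    ref_rank <- rank_of(p_ref)
    dcg_opt <- dcg_at_k(rank_of(p_opt), ref_rank, k)$dcg
    dcg_ew <- dcg_at_k(rank_of(p_ew), ref_rank, k)$dcg
    rows[[r]] <- tibble(
      repetition = r, start = start, dcg_opt = dcg_opt, dcg_ew = dcg_ew,
      win = dcg_opt > dcg_ew
    )
    manifests[[r]] <- list(
      seed = spec_r$seed, densities = spec_r$densities,
      weights = c(w$w0, unname(w$w)), residual = w$residual,
      n_near = attr(w, "fit")$n_near, n_far = attr(w, "fit")$n_far
    )
    if (verbose) {
      message(sprintf(
        "repetition %d (start %s): DCG@%d opt %.4f vs ew %.4f -> %s",
        r, start, k, dcg_opt, dcg_ew, if (dcg_opt > dcg_ew) "win" else "loss"
      ))
    }
    rm(ks)
    gc(verbose = FALSE)
  }
  out <- bind_rows(rows)
  attr(out, "manifest") <- list(
    n_nodes = spec$n_nodes, copy_prob = spec$copy_prob, eta = spec$eta,
    seed = spec$seed, k = k, eps1 = eps1, eps2 = eps2, mapping = mapping,
    restart = restart, solver = solver, max_rows = max_rows,
    repetitions = manifests
  )
  out
}
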