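#' Extract pair scores from a score matrix
#'
#' @param scores A `score_matrix` or plain named square matrix.
#' @param pairs Tibble/data frame with two id columns.
#' @return Numeric vector of scores, one per pair.
#' @export
score_pairs <- function(scores, pairs) {
  s <- if (inherits(scores, "score_matrix")) scores$scores else scores
  i <- match(as.character(pairs[[1]]), rownames(s))
  j <- match(as.character(pairs[[2]]), colnames(s))
  if (anyNA(i) || anyNA(j)) abort("pair endpoints missing from the score matrix")
  s[cbind(i, j)]
}

.n_nonedges <- function(g) {
  n <- length(g$node_ids)
  n * (n - 1) / 2 - n_edges(g)
}

#' ROC curve and AUC for ranked pair recovery
#'
#' Positive pairs (held-out edges) and negative pairs (non-edges) are ranked
#' together by score, descending. The AUC equals the Mann-Whitney statistic
#' (fraction of positive/negative pairs ranked correctly, ties counted one
#' half), and the ROC points are accumulated down the ranked list with tied
#' scores grouped.
#'
#' @param scores A `score_matrix` or named square matrix.
#' @param positives,negatives Disjoint pair tibbles (two id columns).
#' @param label Optional run label carried in the result.
#' @return An `eval_result`: tibble of ROC points (`fpr`, `tpr`) with
#'   attributes `auc`, `n_pos`, `n_neg`, `label`.
#' @export
roc_auc <- function(scores, positives, negatives, label = NA_character_) {
  if (nrow(positives) == 0) abort("empty positive set")
  if (nrow(negatives) == 0) abort("empty negative set")
  sp <- score_pairs(scores, positives)
  sn <- score_pairs(scores, negatives)
  np <- length(sp)
  nn <- length(sn)
  # Mann-Whitney with midranks: half credit for ties
  r <- rank(c(sp, sn), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  # ROC points over the descending ranked list, tied scores as one step
  all_s <- c(sp, sn)
  is_pos <- rep(c(TRUE, FALSE), c(np, nn))
  ord <- order(-all_s)
  s_sorted <- all_s[ord]
  pos_sorted <- is_pos[ord]
  grp_last <- !duplicated(s_sorted, fromLast = TRUE) # last index of each tie group
  tp <- cumsum(pos_sorted)[grp_last] / np
  fp <- cumsum(!pos_sorted)[grp_last] / nn
  pts <- tibble(fpr = c(0, fp), tpr = c(0, tp))
  structure(
    pts,
    auc = auc, n_pos = np, n_neg = nn, label = label,
    class = c("eval_result", class(pts))
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result>%s AUC %.4f (%d positives, %d negatives)\n",
    if (is.na(attr(x, "label"))) "" else paste0(" ", attr(x, "label")),
    attr(x, "auc"), attr(x, "n_pos"), attr(x, "n_neg")
  ))
  invisible(x)
}

#' @export
#' @method $ eval_result
`$.eval_result` <- function(x, name) {
  if (name %in% c("auc", "n_pos", "n_neg", "label")) {
    return(attr(x, name))
  }
  NextMethod()
}

#' @export
glance.eval_result <- function(x, ...) {
  tibble(
    label = attr(x, "label"), auc = attr(x, "auc"),
    n_pos = attr(x, "n_pos"), n_neg = attr(x, "n_neg")
  )
}

#' @export
autoplot.eval_result <- function(object, ...) {
  d <- tibble(fpr = object$fpr, tpr = object$tpr)
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = 3, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.4f", attr(object, "auc"))
    )
}

#' Sample (or enumerate) non-edges as negatives
#'
#' Uniform sample of `n` node pairs absent from the graph's edge set and
#' from `exclude`; with `exhaustive = TRUE` all such non-edges are returned
#' instead.
#'
#' @param g A [ppi_graph].
#' @param n Number of pairs to sample (ignored when `exhaustive`).
#' @param seed Integer seed.
#' @param exclude Optional pair tibble to avoid (e.g. known positives).
#' @param exhaustive Return every available non-edge.
#' @return Tibble of pairs `from`, `to`.
#' @export
negative_sample <- function(g, n, seed = 1, exclude = NULL,
                            exhaustive = FALSE) {
  key <- NULL
  if (!is.null(exclude) && nrow(exclude) > 0) {
    i <- match(as.character(exclude[[1]]), g$node_ids)
    j <- match(as.character(exclude[[2]]), g$node_ids)
    key <- paste(pmin(i, j), pmax(i, j))
  }
  if (exhaustive) {
    nn <- length(g$node_ids)
    full <- which(
      upper.tri(matrix(0, nn, nn)) & as.matrix(g$adjacency) == 0,
      arr.ind = TRUE
    )
    if (!is.null(key)) {
      full <- full[!paste(full[, 1], full[, 2]) %in% key, , drop = FALSE]
    }
    return(tibble(
      from = g$node_ids[full[, 1]], to = g$node_ids[full[, 2]]
    ))
  }
  avail <- .n_nonedges(g) - length(key)
  if (n > avail) {
    abort(sprintf("requested %d negatives but only %d non-edges available", n, avail))
  }
  withr::with_seed(seed, .sample_nonedges(g, n, exclude_key = key))
}

#' Discounted cumulative gain between two rankings
#'
#' Rank-agreement score between a candidate ranking and a reference ranking
#' of the same node set. Relevance is graded by reference position:
#' `rel(v) = k - rank_ref(v)` for nodes in the reference top-k, 0 below it;
#' then `DCG@k = sum_{i=1..k} rel(candidate_i) / log2(i + 1)`. The ideal
#' DCG (candidate = reference) is returned alongside for normalization.
#'
#' @param candidate,reference Character vectors: permutations of the same
#'   node set, best first.
#' @param k Rank depth, at most the set size.
#' @return List with elements `dcg` and `ideal`.
#' @export
dcg_at_k <- function(candidate, reference, k) {
  if (length(candidate) != length(reference) ||
    !setequal(candidate, reference)) {
    abort("candidate and reference must rank the same set")
  }
  if (k > length(reference)) abort("k exceeds the ranking length")
  rel <- pmax(k - match(candidate, reference) + 1 - 1, 0) # k - rank_ref, floored
  disc <- 1 / log2(seq_len(k) + 1)
  ideal_rel <- pmax(k - seq_len(k), 0)
  list(
    dcg = sum(rel[seq_len(k)] * disc),
    ideal = sum(ideal_rel * disc)
  )
}

#' Benchmark learned weights against the two control fusions
#'
#' Evaluates three regularized-Laplacian inferences on the same test
#' positives and sampled negatives: the learned-weight fusion (`WOLP-K`),
#' the bare training network (`G_tn`, weights `(1, 0, ..., 0)`) and the
#' equal-weight fusion (`EW-K`, all weights 1). Optionally repeats the
#' evaluation on the long-range stratum of pairs more than `min_dist` hops
#' apart in the training network.
#'
#' @param g Golden-standard [ppi_graph].
#' @param kernels List of [feature_kernel]s.
#' @param split An `edge_split` of `g` with `connected_train = TRUE`.
#' @param weights Learned `wolp_weights` (or a `wolp_fit`).
#' @param alpha_frac See [regularized_laplacian()].
#' @param neg_ratio Negatives sampled per positive (exhaustive non-edges
#'   are used when the graph is small enough to enumerate).
#' @param seed Seed for negative sampling.
#' @param stratify_distance If not `NULL`, also evaluate the stratum of
#'   pairs with training-network distance strictly greater than this.
#' @return Tibble with columns `label`, `stratum`, `auc`, `n_pos`, `n_neg`;
#'   attribute `"results"` holds the underlying `eval_result`s.
#' @export
run_benchmark <- function(g, kernels, split, weights, alpha_frac = 0.5,
                          neg_ratio = 10, seed = 1,
                          stratify_distance = NULL) {
  if (inherits(weights, "wolp_fit")) weights <- weights$weights
  pos <- split$test
  if (nrow(pos) == 0) abort("split has no test edges")
  n_avail <- .n_nonedges(g)
  exhaustive <- length(g$node_ids) <= 2000 && n_avail <= 50 * nrow(pos)
  neg <- if (exhaustive) {
    negative_sample(g, n = 0, exhaustive = TRUE)
  } else {
    negative_sample(g, n = min(neg_ratio * nrow(pos), n_avail), seed = seed)
  }
  runs <- list(
    `RL_WOLP-K` = weights,
    RL_G_tn = adjacency_only_weights(kernels),
    `RL_EW-K` = equal_weights(kernels)
  )
  strata <- list(all = list(pos = pos, neg = neg))
  if (!is.null(stratify_distance)) {
    tg <- train_graph(split, g)
    strata[[sprintf("dist>%d", stratify_distance)]] <- list(
      pos = pair_distance_filter(tg, pos, stratify_distance),
      neg = pair_distance_filter(tg, neg, stratify_distance)
    )
  }
  out <- list()
  results <- list()
  for (rname in names(runs)) {
    sc <- infer_connected(g, kernels, split, runs[[rname]], alpha_frac)
    for (sname in names(strata)) {
      st <- strata[[sname]]
      if (nrow(st$pos) == 0 || nrow(st$neg) == 0) {
        if (rname == names(runs)[1]) {
          warn(sprintf("stratum '%s' is empty; skipped", sname))
        }
        next
      }
      ev <- roc_auc(sc, st$pos, st$neg, label = rname)
      results[[paste(rname, sname)]] <- ev
      out[[paste(rname, sname)]] <- tibble(
        label = rname, stratum = sname, auc = ev$auc,
        n_pos = ev$n_pos, n_neg = ev$n_neg
      )
    }
  }
  res <- bind_rows(out)
  attr(res, "results") <- results
  res
}
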