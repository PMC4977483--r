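#' Read and write kernel matrices
#'
#' Two plain-text formats are supported. Dense TSV: a header row of node
#' ids, then one row per node with its id in the first column. Sparse
#' coordinate triplets: three tab-separated columns `id  id  value`, with
#' unlisted pairs zero; the matrix is symmetrized by mirroring each triplet.
#' Precomputed kernels arriving from external pipelines are min-max scaled
#' to `[0, 1]` on load.
#'
#' @param path File path.
#' @param name Kernel label; defaults to the file name without extension.
#' @param nodes Node universe for triplet files (dense files carry their
#'   own); also used to check/align dense files when given.
#' @param scale Min-max scale on load (default `TRUE`).
#' @return A [feature_kernel].
#' @export
read_kernel_tsv <- function(path, name = NULL, nodes = NULL, scale = TRUE) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  mat <- as.matrix(tab)
  if (!is.null(nodes)) {
    if (!setequal(rownames(mat), nodes)) {
      abort(sprintf("kernel '%s' nodes do not match the graph universe", path))
    }
    mat <- mat[nodes, nodes, drop = FALSE]
  }
  feature_kernel(mat, name, scale = scale)
}

#' @rdname read_kernel_tsv
#' @export
read_kernel_triplets <- function(path, nodes, name = NULL, scale = TRUE) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(tab) != 3) abort(sprintf("'%s': triplet files need 3 columns", path))
  i <- match(as.character(tab[[1]]), nodes)
  j <- match(as.character(tab[[2]]), nodes)
  if (anyNA(i) || anyNA(j)) {
    abort(sprintf("'%s': triplet ids outside the node universe", path))
  }
  n <- length(nodes)
  mat <- matrix(0, n, n, dimnames = list(nodes, nodes))
  mat[cbind(i, j)] <- tab[[3]]
  mat[cbind(j, i)] <- tab[[3]]
  feature_kernel(mat, name, scale = scale)
}

#' @rdname read_kernel_tsv
#' @param k A [feature_kernel] to write.
#' @param format `"dense"` or `"triplets"`.
#' @export
write_kernel <- function(k, path, format = c("dense", "triplets")) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- data.frame(node = rownames(k$mat), k$mat, check.names = FALSE)
    utils::write.table(tab, path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  } else {
    idx <- which(upper.tri(k$mat) & k$mat != 0, arr.ind = TRUE)
    tab <- data.frame(
      from = rownames(k$mat)[idx[, 1]],
      to = colnames(k$mat)[idx[, 2]],
      value = k$mat[idx]
    )
    utils::write.table(tab, path,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Read or write a fusion weight vector as JSON
#'
#' The JSON object maps `"G_tn"` to `w0` and each kernel name to its
#' weight; fit metadata (residual, solver) rides along under `"_meta"`.
#'
#' @param w A `wolp_weights`.
#' @param path File path.
#' @return `write_weights_json()`: `path` invisibly; `read_weights_json()`:
#'   a `wolp_weights`.
#' @export
write_weights_json <- function(w, path) {
  obj <- c(
    list(G_tn = w$w0), as.list(w$w),
    list(`_meta` = list(residual = w$residual, solver = w$solver))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- obj[["_meta"]]
  obj[["_meta"]] <- NULL
  if (!"G_tn" %in% names(obj)) abort("weights JSON must contain 'G_tn'")
  w <- unlist(obj[names(obj) != "G_tn"])
  weight_vector(
    w0 = obj$G_tn, w = w,
    residual = if (is.null(meta$residual)) NA_real_ else meta$residual,
    solver = if (is.null(meta$solver)) NA_character_ else meta$solver
  )
}

#' Write ranked pair scores as TSV
#'
#' Emits `(u, v, score)` triplets in descending score order, training
#' (masked) pairs omitted.
#'
#' @param scores A `score_matrix`.
#' @param path File path.
#' @param top Optional cap on the number of rows written.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path, top = NULL) {
  tab <- tidy(scores)
  if (!is.null(top)) tab <- head(tab, top)
  utils::write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
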