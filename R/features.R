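#' Fixed-length composition descriptor from a PSSM
#'
#' Bridges a variable-length N x 20 score matrix to one fixed-length
#' sample vector. Each log-odds score is squashed through the logistic
#' function \eqn{s = 1/(1+e^{-x})}, then the length-normalized 20 x 20
#' cross-product matrix \eqn{C = S^T S / N} of the squashed matrix
#' \eqn{S} is flattened row-major into 400 values. Because \eqn{C}
#' depends on rows only through a sum of outer products, the descriptor
#' is invariant to row order and to duplicating all rows.
#'
#' A simpler 20-dimensional alternative (`method = "plain-mean"`, squashed
#' column means) is provided for ablation.
#'
#' @param x A [pssm] object.
#' @param method `"cross-product"` (default, 400-d) or `"plain-mean"`
#'   (20-d column means).
#' @return Numeric vector of length 400 (or 20), named by the protein id
#'   via attribute `protein_id`.
#' @export
pssm_to_composition <- function(x, method = c("cross-product", "plain-mean")) {
  stopifnot(inherits(x, "pssm"))
  method <- match.arg(method)
  s <- 1 / (1 + exp(-x$scores))
  v <- if (method == "cross-product") {
    cmat <- crossprod(s) / nrow(s)
    as.vector(t(cmat))           # row-major flatten
  } else {
    colMeans(s)
  }
  attr(v, "protein_id") <- x$protein_id
  v
}

#' Stack composition descriptors into a design matrix
#'
#' @param vectors List of composition vectors (from
#'   [pssm_to_composition()]) or a list of [pssm] objects (converted on
#'   the fly).
#' @param method Passed to [pssm_to_composition()] when `vectors`
#'   contains PSSMs.
#' @return Numeric matrix, one row per protein in input order, rownames =
#'   protein ids.
#' @export
assemble_design_matrix <- function(vectors, method = "cross-product") {
  stopifnot(length(vectors) >= 1L)
  if (inherits(vectors[[1]], "pssm"))
    vectors <- lapply(vectors, pssm_to_composition, method = method)
  ids <- vapply(vectors, function(v) attr(v, "protein_id"), character(1))
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in design matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  X <- do.call(rbind, lapply(vectors, as.vector))
  rownames(X) <- ids
  X
}

#' Per-pair feature vectors from per-protein embeddings
#'
#' Each labeled pair (a, b) is represented by the concatenation
#' `c(embed(a), embed(b))` in pair-list order, giving a 2d-dimensional
#' vector for d-dimensional protein embeddings. The representation is
#' order-sensitive: (b, a) yields the reversed concatenation.
#' `symmetrize = TRUE` additionally appends every reversed pair with the
#' same label (training augmentation; off by default).
#'
#' @param pairs Data.frame with columns `id_a`, `id_b` and optionally
#'   `label`.
#' @param embeddings Numeric matrix, one row per protein, rownames =
#'   protein ids.
#' @param symmetrize Also emit each pair reversed (default `FALSE`).
#' @return List with `X` (n_pairs x 2d feature matrix) and `y` (integer
#'   labels, or `NULL` when `pairs` has no label column).
#' @export
make_pair_features <- function(pairs, embeddings, symmetrize = FALSE) {
  if (nrow(pairs) == 0L)
    return(list(X = matrix(numeric(0), 0L, 2L * ncol(embeddings)), y = integer(0)))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(embeddings))
  if (length(missing))
    stop("no embedding for id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (symmetrize) {
    rev <- data.frame(id_a = pairs$id_b, id_b = pairs$id_a,
                      stringsAsFactors = FALSE)
    if (!is.null(pairs$label)) rev$label <- pairs$label
    pairs <- rbind(pairs, rev)
  }
  X <- cbind(embeddings[pairs$id_a, , drop = FALSE],
             embeddings[pairs$id_b, , drop = FALSE])
  rownames(X) <- NULL
  colnames(X) <- c(paste0("a", seq_len(ncol(embeddings))),
                   paste0("b", seq_len(ncol(embeddings))))
  list(X = X, y = if (!is.null(pairs$label)) as.integer(pairs$label) else NULL)
}
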