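#' Random disjoint feature-subset partition
#'
#' Shuffles the feature indices `1..m` and splits them into K contiguous
#' chunks of size `m %/% K`, with the first `m %% K` chunks receiving one
#' extra index, so subsets always partition the full index set.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param m Number of features.
#' @param K Number of subsets (1 <= K <= m).
#' @return List of K integer vectors.
#' @export
partition_features <- function(m, K) {
  m <- as.integer(m); K <- as.integer(K)
  if (K < 1L || K > m)
    stop("K must satisfy 1 <= K <= m (m = ", m, ")", call. = FALSE)
  perm <- sample.int(m)
  base <- m %/% K
  extra <- m %% K
  sizes <- rep(base, K) + c(rep(1L, extra), rep(0L, K - extra))
  split(perm, rep(seq_len(K), times = sizes))
}

#' Build one sparse rotation matrix
#'
#' For each feature subset, draws a bootstrap sample of
#' `ceiling(bootstrap_fraction * n)` training rows (with replacement by
#' default), runs a full-rank PCA on those rows restricted to the
#' subset's columns, and places the loading matrix as that subset's
#' diagonal block, permuted back to original feature order. All principal
#' components are retained, so the result is a pure rotation: `t(F) %*% F
#' = I` and row norms are preserved. A subset whose bootstrap sample has
#' zero variance falls back to an identity block.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param S Numeric n x m training matrix.
#' @param subsets Partition from [partition_features()].
#' @param bootstrap_fraction Fraction of rows drawn per subset (default
#'   0.75).
#' @param replace Draw with replacement (bootstrap, default) or without
#'   (subsample).
#' @return Object of class `"rotation_matrix"`: list with `F` (m x m) and
#'   `subsets`.
#' @export
build_rotation_matrix <- function(S, subsets, bootstrap_fraction = 0.75,
                                  replace = TRUE) {
  S <- as.matrix(S)
  n <- nrow(S); m <- ncol(S)
  stopifnot(n >= 2L, bootstrap_fraction > 0, bootstrap_fraction <= 1)
  if (!setequal(unlist(subsets), seq_len(m)))
    stop("subsets must partition 1..m", call. = FALSE)
  Fm <- matrix(0, m, m)
  n_boot <- ceiling(bootstrap_fraction * n)
  for (idx in subsets) {
    rows <- sample.int(n, n_boot, replace = replace)
    block <- S[rows, idx, drop = FALSE]
    if (all(apply(block, 2L, stats::var) < .Machine$double.eps)) {
      Fm[idx, idx] <- diag(length(idx))
    } else {
      rot <- stats::prcomp(block, center = TRUE, scale. = FALSE)$rotation
      if (ncol(rot) < length(idx)) {
        # prcomp drops axes when n_boot <= p; complete to an orthonormal basis
        full <- qr.Q(qr(cbind(rot, diag(length(idx)))))[, seq_along(idx)]
        rot <- full
      }
      Fm[idx, idx] <- rot
    }
  }
  structure(list(F = Fm, subsets = subsets), class = "rotation_matrix")
}

#' Fit a Rotation Forest ensemble
#'
#' Trains L CART decision trees, each on the training data rotated by its
#' own sparse rotation matrix: the feature set is randomly partitioned
#' into K disjoint subsets, a PCA basis is computed per subset from a 75%
#' bootstrap sample, and the per-subset loadings are assembled
#' block-diagonally ([build_rotation_matrix()]). Every tree sees all
#' training rows (rotated); diversity comes from the random partitions
#' and bootstrap PCA bases. Class posteriors of the ensemble are the
#' average of the per-tree posteriors.
#'
#' Binary classification only; labels must be 0/1 with both classes
#' present. Trees are grown to purity (Gini splits, `cp = 0`,
#' `minsplit = 2`).
#'
#' @param X Numeric n x m feature matrix.
#' @param y Integer/numeric vector of 0/1 labels.
#' @param K Number of feature subsets (default 5).
#' @param L Number of trees (default 5).
#' @param bootstrap_fraction Row fraction for per-subset PCA (default
#'   0.75).
#' @param replace Bootstrap with replacement (default) or subsample.
#' @param seed Optional integer; when supplied, seeds the RNG so the fit
#'   is bit-reproducible.
#' @param control Optional [rpart::rpart.control()] overriding the
#'   default fully-grown trees.
#' @return Object of class `"rotation_forest"`.
#' @export
rotation_forest <- function(X, y, K = 5L, L = 5L, bootstrap_fraction = 0.75,
                            replace = TRUE, seed = NULL, control = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("both classes (0 and 1) must be present in y", call. = FALSE)
  m <- ncol(X)
  K <- as.integer(K); L <- as.integer(L)
  stopifnot(L >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(control))
    control <- rpart::rpart.control(minsplit = 2L, cp = 0, xval = 0L,
                                    maxdepth = 30L, maxcompete = 0L,
                                    maxsurrogate = 0L)
  yf <- factor(y, levels = c(0L, 1L))
  members <- vector("list", L)
  for (i in seq_len(L)) {
    subsets <- partition_features(m, K)
    rot <- build_rotation_matrix(X, subsets, bootstrap_fraction, replace)
    Xr <- X %*% rot$F
    df <- as.data.frame(Xr)
    names(df) <- paste0("f", seq_len(m))
    df$.y <- yf
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         control = control,
                         parms = list(split = "gini"))
    members[[i]] <- list(rotation = rot, tree = tree)
  }
  structure(list(members = members, K = K, L = L,
                 bootstrap_fraction = bootstrap_fraction,
                 replace = replace, m = m, classes = c(0L, 1L)),
            class = "rotation_forest")
}

#' Class posteriors of a rotation forest
#'
#' The posterior for class j is the average over the L trees of each
#' tree's class-j probability evaluated on that tree's rotated input;
#' rows sum to 1.
#'
#' @param model A fitted [rotation_forest()].
#' @param X Numeric q x m matrix.
#' @return q x 2 matrix with columns `"0"` and `"1"`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "rotation_forest"))
  X <- as.matrix(X)
  if (ncol(X) != model$m)
    stop("X has ", ncol(X), " features; model was fitted on ", model$m,
         call. = FALSE)
  acc <- matrix(0, nrow(X), 2L, dimnames = list(NULL, c("0", "1")))
  for (mem in model$members) {
    Xr <- X %*% mem$rotation$F
    df <- as.data.frame(Xr)
    names(df) <- paste0("f", seq_len(model$m))
    p <- stats::predict(mem$tree, newdata = df, type = "prob")
    acc <- acc + p[, c("0", "1"), drop = FALSE]
  }
  acc / model$L
}

#' Predicted labels of a rotation forest
#'
#' Argmax of the averaged posterior; an exact tie at 0.5 is resolved to
#' class 0 (the conservative non-interaction call).
#'
#' @param object A fitted [rotation_forest()].
#' @param newdata Numeric q x m matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer labels, or the posterior matrix for `type = "prob"`.
#' @export
predict.rotation_forest <- function(object, newdata, type = c("class", "prob"),
                                    ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  as.integer(p[, "1"] > 0.5)
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("Rotation forest: L = %d trees, K = %d feature subsets, %d features\n",
              x$L, x$K, x$m))
  invisible(x)
}
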