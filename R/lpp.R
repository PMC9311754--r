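#' Symmetrized k-nearest-neighbor heat-kernel graph
#'
#' Links samples i and j when i is among the k nearest neighbors of j or
#' vice versa (Euclidean distance), and weights linked edges with the
#' heat kernel \eqn{P_{ij} = \exp(-\|x_i-x_j\|^2 / t)}. With
#' `heat_scale = "auto"` the scale t is the mean squared distance over
#' linked edges, so typical linked weights sit near \eqn{e^{-1}}.
#'
#' @param X Numeric n x m matrix, samples as rows, finite entries.
#' @param k_nn Number of nearest neighbors (must be < n).
#' @param heat_scale Positive scale t of the heat kernel, or `"auto"`.
#' @return Object of class `"lpp_graph"`: list with `P` (n x n symmetric
#'   weight matrix, zero diagonal), `degree` (vector of row sums of `P`),
#'   `laplacian` (`diag(degree) - P`) and `heat_scale` (the t used).
#' @export
build_graph <- function(X, k_nn = 5L, heat_scale = "auto") {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2L, all(is.finite(X)))
  k_nn <- as.integer(k_nn)
  if (k_nn < 1L || k_nn >= n)
    stop("k_nn must satisfy 1 <= k_nn < n (n = ", n, ")", call. = FALSE)
  d2 <- as.matrix(stats::dist(X))^2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    # nearest neighbors of i, excluding i; ties broken by index for determinism
    ord <- order(d2[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k_nn)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  if (identical(heat_scale, "auto")) {
    t_use <- mean(d2[adj])
    if (!is.finite(t_use) || t_use <= 0) t_use <- 1
  } else {
    t_use <- as.numeric(heat_scale)
    stopifnot(is.finite(t_use), t_use > 0)
  }
  P <- matrix(0, n, n)
  P[adj] <- exp(-d2[adj] / t_use)
  deg <- rowSums(P)
  structure(list(P = P, degree = deg, laplacian = diag(deg) - P,
                 heat_scale = t_use, k_nn = k_nn),
            class = "lpp_graph")
}

#' Fit Locality Preserving Projections
#'
#' Learns a linear map that preserves local neighborhood structure: it
#' minimizes \eqn{\sum_{ij} (y_i - y_j)^2 P_{ij}} over projections
#' \eqn{y_i = W^T x_i}, subject to \eqn{w^T X D X^T w = 1}, which reduces
#' to the generalized eigenproblem
#' \deqn{X L X^T w = \lambda X D X^T w}
#' with L = D - P the graph Laplacian and D the diagonal degree matrix.
#' The `out_dim` eigenvectors of smallest eigenvalue form the projection.
#'
#' Columns of `X` are mean-centered before the eigenproblem (removes the
#' trivial constant direction). The eigenproblem is solved on the span of
#' the centered training data (obtained by singular value decomposition):
#' when n < m — routine here, with 400-dimensional descriptors — the
#' null space of the data otherwise contributes spurious zero-eigenvalue
#' directions that are unconstrained on training samples but explode on
#' out-of-sample inputs. Within the span, the right-hand matrix is
#' ridge-regularized and the problem solved by Cholesky whitening
#' followed by a dense symmetric eigendecomposition. Each returned
#' eigenvector is rescaled to satisfy the unit constraint and
#' sign-canonicalized (largest-magnitude entry positive) so results are
#' deterministic across platforms. If the requested dimension exceeds the
#' data rank, the trailing columns are zero (constant embedding
#' directions).
#'
#' @param X Numeric n x m matrix, samples as rows (internally transposed
#'   to the samples-as-columns convention of the eigenproblem above).
#' @param out_dim Embedding dimension l (<= min(n, m)).
#' @param k_nn,heat_scale Passed to [build_graph()].
#' @param eps Ridge added to the right-hand matrix; `"auto"` (default)
#'   uses `1e-6 * trace(X D X^T) / m`. Set `eps = 0` to solve the
#'   unregularized problem (errors if it is numerically singular).
#' @param graph Optionally a precomputed [build_graph()] result.
#' @return Object of class `"lpp"`: `W` (m x l projection, columns =
#'   eigenvectors, eigenvalues ascending), `eigenvalues`, `means` (fitted
#'   column means), `graph`, and the configuration.
#' @seealso [predict.lpp()] to embed new samples.
#' @export
fit_lpp <- function(X, out_dim, k_nn = 5L, heat_scale = "auto",
                    eps = "auto", graph = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  stopifnot(n >= 2L, all(is.finite(X)))
  out_dim <- as.integer(out_dim)
  if (out_dim < 1L || out_dim > min(n, m))
    stop("out_dim must be in 1..min(n, m) = ", min(n, m), call. = FALSE)
  if (is.null(graph)) graph <- build_graph(X, k_nn = k_nn, heat_scale = heat_scale)
  stopifnot(inherits(graph, "lpp_graph"), nrow(graph$P) == n)

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  # restrict to the span of the centered data: with n < m the null space
  # holds zero-eigenvalue directions that blow up on out-of-sample points
  sv <- svd(Xc, nu = 0)
  r <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
  if (r == 0L) {
    # all rows identical: every projection is constant; return zero map
    W <- matrix(0, m, out_dim)
    return(structure(list(W = W, eigenvalues = rep(0, out_dim), means = mu,
                          graph = graph, out_dim = out_dim,
                          k_nn = graph$k_nn, heat_scale = graph$heat_scale,
                          eps = 0, rank = 0L, n_train = n, in_dim = m),
                     class = "lpp"))
  }
  V <- sv$v[, seq_len(r), drop = FALSE]
  Xr <- Xc %*% V                        # n x r, full column rank
  # samples are rows here; in the samples-as-columns convention of the
  # eigenproblem, X L X^T becomes Xr' L Xr
  A  <- crossprod(Xr, graph$laplacian %*% Xr)
  B0 <- crossprod(Xr, graph$degree * Xr)
  A  <- (A + t(A)) / 2
  B0 <- (B0 + t(B0)) / 2
  if (identical(eps, "auto")) {
    eps_use <- 1e-6 * sum(diag(B0)) / r
    if (eps_use <= 0) eps_use <- 1e-8
  } else {
    eps_use <- as.numeric(eps)
    stopifnot(eps_use >= 0)
  }
  B <- B0 + diag(eps_use, r)
  R <- tryCatch(chol(B), error = function(e)
    stop("right-hand matrix X D X^T is numerically singular; ",
         "use eps > 0 (got eps = ", eps_use, ")", call. = FALSE))
  Rinv <- backsolve(R, diag(r))
  M <- crossprod(Rinv, A %*% Rinv)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)      # eigenvalues descending
  ord <- rev(seq_len(r))                # ascending eigenvalue, then solver index
  l_eff <- min(out_dim, r)
  vals <- es$values[ord][seq_len(l_eff)]
  W <- (V %*% (Rinv %*% es$vectors[, ord, drop = FALSE]))[,
         seq_len(l_eff), drop = FALSE]
  # unit constraint w' (X D X') w = 1, then deterministic sign
  B0_full <- crossprod(Xc, graph$degree * Xc)
  for (j in seq_len(l_eff)) {
    q <- drop(crossprod(W[, j], B0_full %*% W[, j]))
    if (q > 1e-12) W[, j] <- W[, j] / sqrt(q)
    i_max <- which.max(abs(W[, j]))
    if (W[i_max, j] < 0) W[, j] <- -W[, j]
  }
  if (l_eff < out_dim) {                # rank-deficient: pad constant dims
    W <- cbind(W, matrix(0, m, out_dim - l_eff))
    vals <- c(vals, rep(0, out_dim - l_eff))
  }
  structure(list(W = W, eigenvalues = vals, means = mu, graph = graph,
                 rank = r,
                 out_dim = out_dim, k_nn = graph$k_nn,
                 heat_scale = graph$heat_scale, eps = eps_use,
                 n_train = n, in_dim = m),
            class = "lpp")
}

#' Embed samples with a fitted LPP model
#'
#' Applies \eqn{y = W^T (x - \bar{x})} using the projection and column
#' means learned by [fit_lpp()].
#'
#' @param object A fitted `"lpp"` model.
#' @param newdata Numeric q x m matrix (m must match the fitted input
#'   dimension).
#' @param ... Unused.
#' @return q x l embedding matrix (rownames carried over).
#' @export
predict.lpp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$in_dim)
    stop("newdata has ", ncol(newdata), " columns; model was fitted on ",
         object$in_dim, call. = FALSE)
  sweep(newdata, 2L, object$means) %*% object$W
}

#' @export
print.lpp <- function(x, ...) {
  cat(sprintf("LPP model: %d -> %d dims, n_train = %d, k_nn = %d, t = %.4g, eps = %.3g\n",
              x$in_dim, x$out_dim, x$n_train, x$k_nn, x$heat_scale, x$eps))
  invisible(x)
}

#' Locality-preserving objective of an embedding
#'
#' Evaluates \eqn{\frac12 \sum_{ij} (y_i - y_j)^2 P_{ij}} for a
#' one-dimensional embedding y over a graph, the quantity LPP minimizes;
#' it equals \eqn{w^T X L X^T w} for \eqn{y = X^T w}. Exposed for
#' diagnostics and testing of that identity.
#'
#' @param y Numeric vector of per-sample embedding values.
#' @param graph An `"lpp_graph"`.
#' @return The scalar objective value.
#' @export
lpp_objective <- function(y, graph) {
  stopifnot(inherits(graph, "lpp_graph"), length(y) == nrow(graph$P))
  0.5 * sum(outer(y, y, "-")^2 * graph$P)
}
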