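# Independent oracles and small fixture builders shared across tests.

# Random small PSSM with integer scores in the realistic clipped range.
random_pssm <- function(id, n_rows, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pssm(id, matrix(sample(-10:12, n_rows * 20L, replace = TRUE), n_rows, 20L))
}

# Brute-force two-loop composition oracle: squash, then C[j,k] by explicit
# summation, flattened row-major.
composition_oracle <- function(scores) {
  s <- 1 / (1 + exp(-scores))
  n <- nrow(scores)
  out <- numeric(400)
  for (j in 1:20) for (k in 1:20) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + s[i, j] * s[i, k]
    out[(j - 1) * 20 + k] <- acc / n
  }
  out
}

# Dense generalized-eigenproblem oracle for LPP. The span restriction is
# obtained from an eigendecomposition of the m x m Gram matrix and the
# whitening from an eigendecomposition-based inverse square root — both a
# different route from the fitting code's SVD + Cholesky.
lpp_dense_oracle <- function(X, out_dim, graph, eps = "auto") {
  X <- as.matrix(X)
  m <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  r <- sum(eg$values > max(eg$values[1], .Machine$double.eps) * 1e-20)
  V <- eg$vectors[, seq_len(r), drop = FALSE]
  Xr <- Xc %*% V
  A <- t(Xr) %*% graph$laplacian %*% Xr
  B0 <- t(Xr) %*% (graph$degree * Xr)
  A <- (A + t(A)) / 2; B0 <- (B0 + t(B0)) / 2
  if (identical(eps, "auto")) {
    eps <- 1e-6 * sum(diag(B0)) / r
    if (eps <= 0) eps <- 1e-8
  }
  B <- B0 + diag(eps, r)
  eb <- eigen(B, symmetric = TRUE)
  Bih <- eb$vectors %*% diag(1 / sqrt(eb$values), r) %*% t(eb$vectors)
  es <- eigen(Bih %*% A %*% Bih, symmetric = TRUE)
  ord <- rev(seq_len(r))
  l_eff <- min(out_dim, r)
  W <- (V %*% (Bih %*% es$vectors[, ord, drop = FALSE]))[, seq_len(l_eff),
                                                         drop = FALSE]
  vals <- es$values[ord][seq_len(l_eff)]
  A_full <- t(Xc) %*% graph$laplacian %*% Xc
  B0_full <- t(Xc) %*% (graph$degree * Xc)
  for (j in seq_len(l_eff)) {
    q <- drop(t(W[, j]) %*% B0_full %*% W[, j])
    if (q > 1e-12) W[, j] <- W[, j] / sqrt(q)
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, values = vals, A = (A_full + t(A_full)) / 2,
       B0 = (B0_full + t(B0_full)) / 2, eps = eps, Xc = Xc, rank = r)
}

# Max abs deviation between two column sets up to per-column sign.
max_dev_up_to_sign <- function(W1, W2) {
  max(vapply(seq_len(ncol(W1)), function(j)
    min(max(abs(W1[, j] - W2[, j])), max(abs(W1[, j] + W2[, j]))),
    numeric(1)))
}

# Exhaustive pair-counting AUC oracle: (concordant + 0.5 * tied) pairs
# over n_pos * n_neg.
auc_concordance <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Direct arithmetic metric oracle.
metrics_direct <- function(tp, tn, fp, fn, dialect) {
  prec_den <- if (dialect == "as_printed") tn + fp else tp + fp
  prec_num <- if (dialect == "as_printed") tn else tp
  den <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn) * sqrt(tp + fp)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (prec_den == 0) 0 else prec_num / prec_den,
    sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Small complete synthetic dataset, cached per test file run.
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_ppi_data(synthetic_config(
        n_proteins = 40L, n_pos_pairs = 60L, n_neg_pairs = 60L,
        n_modules = 6L, latent_dim = 6L, seed = 11L))
    cache
  }
})
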