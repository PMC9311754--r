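#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length 0/1 vectors; class 1 is positive
#'   (interacting).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L))
}

#' Classification metrics from a confusion table
#'
#' Computes accuracy, precision, sensitivity and the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FN)(TN+FP)(TN+FN)(TP+FP)}}.}
#'
#' Two precision dialects are supported, because published PPI work in
#' this family sometimes tabulates specificity under the heading
#' "precision": `"as_printed"` (default) reports
#' \eqn{TN/(TN+FP)} (specificity) for direct comparison with such
#' tables, while `"standard"` reports the usual \eqn{TP/(TP+FP)}.
#' Accuracy, sensitivity and MCC are identical in both dialects. A
#' metric whose denominator is 0 is reported as 0 and listed in the
#' `undefined` attribute.
#'
#' @param ct Named counts from [confusion_counts()].
#' @param dialect `"as_printed"` or `"standard"`.
#' @return Named numeric vector `c(accuracy, precision, sensitivity,
#'   mcc)` with attributes `dialect` and `undefined`.
#' @export
compute_metrics <- function(ct, dialect = c("as_printed", "standard")) {
  dialect <- match.arg(dialect)
  tp <- as.numeric(ct[["TP"]]); tn <- as.numeric(ct[["TN"]])
  fp <- as.numeric(ct[["FP"]]); fn <- as.numeric(ct[["FN"]])
  total <- tp + tn + fp + fn
  stopifnot(total > 0)
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); 0 } else num / den
  }
  acc <- (tp + tn) / total
  prec <- if (dialect == "as_printed") safe(tn, tn + fp, "precision")
          else safe(tp, tp + fp, "precision")
  sen <- safe(tp, tp + fn, "sensitivity")
  mcc_den <- sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn)) * sqrt((tp + fp))
  mcc <- if (mcc_den == 0) { undef <- c(undef, "mcc"); 0 }
         else (tp * tn - fp * fn) / mcc_den
  out <- c(accuracy = acc, precision = prec, sensitivity = sen, mcc = mcc)
  attr(out, "dialect") <- dialect
  attr(out, "undefined") <- undef
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique scores (each point: predict
#' class 1 when score >= threshold), computing TPR = TP/(TP+FN) and
#' FPR = FP/(FP+TN), and integrates the curve with the trapezoid rule.
#' The curve always starts at (0, 0) and ends at (1, 1).
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores Class-1 posterior scores.
#' @return Object of class `"roc_curve"`: list with `points` (data.frame
#'   `fpr`, `tpr`, non-decreasing fpr) and `auc`.
#' @export
roc_and_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(y_true %in% 0:1))
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both classes in y_true", call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tpr[i] <- sum(pred & y_true == 1L) / n_pos
    fpr[i] <- sum(pred & y_true == 0L) / n_neg
  }
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the tunable settings of the PSSM -> composition -> LPP ->
#' rotation-forest pipeline. Defaults follow the method's headline
#' settings: per-protein embedding dimension 20 for the compact synthetic
#' benchmark (use 40 for yeast-scale data, 80 for H. pylori-scale data),
#' K = 5 feature subsets and L = 5 trees, 5 nearest neighbors in the LPP
#' graph with automatic heat scale.
#'
#' `transductive = TRUE` fits LPP on descriptors of all proteins
#' (including test-fold proteins); the default `FALSE` fits it on
#' training-fold proteins only, the leakage-free protocol.
#'
#' @param out_dim Per-protein LPP embedding dimension (pair vectors have
#'   2 * out_dim features).
#' @param k_nn,heat_scale,eps LPP graph/eigenproblem settings, see
#'   [fit_lpp()].
#' @param K,L,bootstrap_fraction Rotation-forest settings, see
#'   [rotation_forest()].
#' @param dialect Metric dialect, see [compute_metrics()].
#' @param transductive Fit LPP on all proteins rather than training-fold
#'   proteins only.
#' @param composition Descriptor method, see [pssm_to_composition()].
#' @return List of class `"ppi_pipeline_config"`.
#' @export
pipeline_config <- function(out_dim = 20L, k_nn = 5L, heat_scale = "auto",
                            eps = "auto", K = 5L, L = 5L,
                            bootstrap_fraction = 0.75,
                            dialect = "as_printed", transductive = FALSE,
                            composition = "cross-product") {
  structure(list(out_dim = as.integer(out_dim), k_nn = as.integer(k_nn),
                 heat_scale = heat_scale, eps = eps, K = as.integer(K),
                 L = as.integer(L),
                 bootstrap_fraction = as.numeric(bootstrap_fraction),
                 dialect = dialect, transductive = isTRUE(transductive),
                 composition = composition),
            class = "ppi_pipeline_config")
}

# Fit LPP + rotation forest on training pairs, score test pairs.
# Returns list(metrics, auc, roc, scores, y_test).
.fit_and_score <- function(X_desc, train_pairs, test_pairs, config, seed) {
  lpp_ids <- if (config$transductive) rownames(X_desc)
             else unique(c(train_pairs$id_a, train_pairs$id_b))
  X_fit <- X_desc[lpp_ids, , drop = FALSE]
  k_use <- min(config$k_nn, nrow(X_fit) - 1L)
  d_use <- min(config$out_dim, nrow(X_fit), ncol(X_fit))
  model_lpp <- fit_lpp(X_fit, out_dim = d_use, k_nn = k_use,
                       heat_scale = config$heat_scale, eps = config$eps)
  emb <- predict(model_lpp, X_desc)
  train_feat <- make_pair_features(train_pairs, emb)
  test_feat <- make_pair_features(test_pairs, emb)
  forest <- rotation_forest(train_feat$X, train_feat$y,
                            K = min(config$K, ncol(train_feat$X)),
                            L = config$L,
                            bootstrap_fraction = config$bootstrap_fraction,
                            seed = seed)
  scores <- predict_proba(forest, test_feat$X)[, "1"]
  y_pred <- as.integer(scores > 0.5)
  ct <- confusion_counts(test_feat$y, y_pred)
  roc <- roc_and_auc(test_feat$y, scores)
  list(metrics = compute_metrics(ct, config$dialect), counts = ct,
       auc = roc$auc, roc = roc, scores = scores, y_test = test_feat$y,
       lpp = model_lpp, forest = forest)
}

# Stratified fold assignment: per class, shuffled indices dealt round-robin.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("fewer than k = ", k, " pairs in class ", cl, call. = FALSE)
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold: composition descriptors are computed for all proteins,
#' LPP is fitted on the training-fold proteins (or all proteins when
#' `config$transductive`), every protein is embedded with the fitted
#' projection, pair features are concatenated embeddings, a rotation
#' forest is trained on the training pairs and evaluated on the held-out
#' pairs. Folds are stratified on the pair label. All randomness (fold
#' assignment, rotation-forest fits) flows from `seed`.
#'
#' @param pssms List of [pssm] objects covering every id in `pairs`.
#' @param pairs Labeled pair data.frame (`id_a`, `id_b`, `label`).
#' @param config A [pipeline_config()].
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `"ppi_cv"`: `folds` (per-fold metric
#'   data.frame), `mean`, `sd`, `fold_assignment`, `config`.
#' @export
cross_validate <- function(pssms, pairs, config = pipeline_config(),
                           k_folds = 5L, seed = 1L) {
  stopifnot(inherits(config, "ppi_pipeline_config"), nrow(pairs) >= k_folds)
  X_desc <- assemble_design_matrix(pssms, method = config$composition)
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(X_desc))
  if (length(missing))
    stop("pairs reference proteins without PSSMs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(seed)
  fold <- .stratified_folds(pairs$label, k_folds)
  rows <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    res <- .fit_and_score(X_desc, pairs[fold != f, , drop = FALSE],
                          pairs[fold == f, , drop = FALSE],
                          config, seed = (seed %% 21000000L) * 100L + f)
    rows[[f]] <- data.frame(fold = f, n_test = sum(fold == f),
                            accuracy = res$metrics[["accuracy"]],
                            precision = res$metrics[["precision"]],
                            sensitivity = res$metrics[["sensitivity"]],
                            mcc = res$metrics[["mcc"]],
                            auc = res$auc)
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "sensitivity", "mcc", "auc")
  structure(list(folds = folds,
                 mean = colMeans(folds[metric_cols]),
                 sd = vapply(folds[metric_cols], stats::sd, numeric(1)),
                 fold_assignment = fold, k_folds = k_folds, seed = seed,
                 config = config),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (%d pairs, seed %d)\n",
              x$k_folds, length(x$fold_assignment), x$seed))
  print(round(x$folds[-1], digits))
  cat("mean:\n"); print(round(x$mean, digits))
  cat("sd:\n"); print(round(x$sd, digits))
  invisible(x)
}

#' Cross-validated sweep over embedding dimensions
#'
#' Repeats [cross_validate()] for each per-protein embedding dimension
#' and tabulates mean and standard deviation of every metric, mirroring
#' the usual dimension-selection table of this method family.
#'
#' @param pssms,pairs,config,k_folds,seed As in [cross_validate()].
#' @param dims Integer vector of per-protein embedding dimensions.
#' @return Data.frame with one row per dimension: `dim`, then
#'   `<metric>_mean` and `<metric>_sd` columns.
#' @export
dimension_sweep <- function(pssms, pairs, dims, config = pipeline_config(),
                            k_folds = 5L, seed = 1L) {
  rows <- lapply(dims, function(d) {
    cfg <- config
    cfg$out_dim <- as.integer(d)
    cv <- cross_validate(pssms, pairs, cfg, k_folds = k_folds, seed = seed)
    data.frame(dim = d,
               accuracy_mean = cv$mean[["accuracy"]], accuracy_sd = cv$sd[["accuracy"]],
               precision_mean = cv$mean[["precision"]], precision_sd = cv$sd[["precision"]],
               sensitivity_mean = cv$mean[["sensitivity"]], sensitivity_sd = cv$sd[["sensitivity"]],
               mcc_mean = cv$mean[["mcc"]], mcc_sd = cv$sd[["mcc"]],
               auc_mean = cv$mean[["auc"]], auc_sd = cv$sd[["auc"]])
  })
  do.call(rbind, rows)
}

#' Train on one dataset, test on an independent one
#'
#' Fits the LPP embedding and rotation forest on the training proteins
#' and pairs only, embeds the test proteins with the fitted projection,
#' and reports metrics on the test pairs — the cross-species protocol
#' where a model trained on one organism is evaluated on another's pairs.
#'
#' @param train_pssms,train_pairs Training PSSMs and labeled pairs.
#' @param test_pssms,test_pairs Independent test PSSMs and labeled pairs
#'   (ids may be disjoint from training; the PSSM column convention must
#'   match).
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the rotation-forest fit.
#' @return List with `metrics`, `counts`, `auc`, `roc`, `scores`.
#' @export
independent_test <- function(train_pssms, train_pairs, test_pssms, test_pairs,
                             config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(config, "ppi_pipeline_config"))
  X_train <- assemble_design_matrix(train_pssms, method = config$composition)
  X_test <- assemble_design_matrix(test_pssms, method = config$composition)
  k_use <- min(config$k_nn, nrow(X_train) - 1L)
  d_use <- min(config$out_dim, nrow(X_train), ncol(X_train))
  set.seed(seed)
  model_lpp <- fit_lpp(X_train, out_dim = d_use, k_nn = k_use,
                       heat_scale = config$heat_scale, eps = config$eps)
  train_feat <- make_pair_features(train_pairs, predict(model_lpp, X_train))
  test_feat <- make_pair_features(test_pairs, predict(model_lpp, X_test))
  forest <- rotation_forest(train_feat$X, train_feat$y,
                            K = min(config$K, ncol(train_feat$X)),
                            L = config$L,
                            bootstrap_fraction = config$bootstrap_fraction,
                            seed = seed)
  scores <- predict_proba(forest, test_feat$X)[, "1"]
  ct <- confusion_counts(test_feat$y, as.integer(scores > 0.5))
  roc <- roc_and_auc(test_feat$y, scores)
  list(metrics = compute_metrics(ct, config$dialect), counts = ct,
       auc = roc$auc, roc = roc, scores = scores)
}
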