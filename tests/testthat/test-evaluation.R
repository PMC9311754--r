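test_that("confusion counts enumerate the four cells", {
  ct <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(ct, c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  same <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(same[["FP"]] + same[["FN"]], 0L)
  allfp <- confusion_counts(rep(0, 5), rep(1, 5))
  expect_identical(allfp[["FP"]], 5L)
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths")
})

test_that("metrics reproduce hand-computed confusion-table values", {
  perfect <- compute_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1))
  mixed <- compute_metrics(c(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(mixed[["accuracy"]], 0.5)
  expect_equal(mixed[["mcc"]], 0)
  ct <- c(TP = 90, TN = 80, FP = 20, FN = 10)
  m <- compute_metrics(ct)
  expect_equal(m[["mcc"]], 7000 / sqrt(99e6), tolerance = 1e-12)
  expect_equal(m[["sensitivity"]], 0.9)
  expect_equal(m[["precision"]], 0.8)           # as-printed: TN/(TN+FP)
  expect_equal(compute_metrics(ct, "standard")[["precision"]], 90 / 110)
})

test_that("zero denominators report 0 with an undefined flag", {
  m <- compute_metrics(c(TP = 0, TN = 5, FP = 0, FN = 0), "standard")
  expect_identical(m[["precision"]], 0)
  expect_true("precision" %in% attr(m, "undefined"))
  expect_true("mcc" %in% attr(m, "undefined"))
})

test_that("dialects agree whenever TP=TN and FP=FN", {
  for (tp in c(1, 5)) for (fp in c(0, 3)) {
    ct <- c(TP = tp, TN = tp, FP = fp, FN = fp)
    expect_equal(compute_metrics(ct, "as_printed"),
                 compute_metrics(ct, "standard"), ignore_attr = TRUE)
  }
})

test_that("ROC endpoints and degenerate scores behave as defined", {
  r1 <- roc_and_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(r1$auc, 1)
  r2 <- roc_and_auc(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(r2$points[nrow(r2$points), ]), c(fpr = 1, tpr = 1))
  expect_error(roc_and_auc(c(1, 1), c(0.2, 0.7)), "both classes")
})

test_that("AUC equals the concordance oracle on the six-point hand example", {
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  expect_equal(roc_and_auc(y, s)$auc, auc_concordance(y, s), tolerance = 1e-12)
  expect_equal(auc_concordance(y, s), (8 + 0) / 9, tolerance = 0)
})

test_that("AUC matches the pair-counting oracle on random small inputs", {
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)   # rounded to force ties sometimes
    expect_equal(roc_and_auc(y, s)$auc, auc_concordance(y, s),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  s <- runif(40)
  expect_equal(roc_and_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("stratified folds partition pairs with balanced class ratios", {
  d <- small_benchmark()
  cv <- cross_validate(d$pssms, d$pairs,
                       pipeline_config(out_dim = 5, k_nn = 3), seed = 2)
  fold <- cv$fold_assignment
  expect_identical(length(fold), nrow(d$pairs))
  expect_setequal(unique(fold), 1:5)
  per_fold_pos <- tapply(d$pairs$label, fold, sum)
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 1)
})

test_that("cross-validation is reproducible and returns sane aggregates", {
  d <- small_benchmark()
  cfg <- pipeline_config(out_dim = 5, k_nn = 3)
  cv1 <- cross_validate(d$pssms, d$pairs, cfg, seed = 3)
  cv2 <- cross_validate(d$pssms, d$pairs, cfg, seed = 3)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(nrow(cv1$folds), 5L)
  expect_true(all(cv1$folds$accuracy >= 0 & cv1$folds$accuracy <= 1))
  expect_true(all(abs(cv1$mean) <= 1))
})

test_that("the dimension sweep emits one row per dimension with the full schema", {
  d <- small_benchmark()
  tab <- dimension_sweep(d$pssms, d$pairs, dims = c(2, 4),
                         pipeline_config(out_dim = 5, k_nn = 3), seed = 4)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$dim, c(2, 4))
  expect_true(all(c("accuracy_mean", "accuracy_sd", "precision_mean",
                    "sensitivity_mean", "mcc_mean", "auc_mean", "auc_sd")
                  %in% names(tab)))
  tab2 <- dimension_sweep(d$pssms, d$pairs, dims = c(2, 4),
                          pipeline_config(out_dim = 5, k_nn = 3), seed = 4)
  expect_identical(tab, tab2)
})

test_that("independent testing is label-symmetric and leakage-free", {
  d <- small_benchmark()
  test_cfg <- synthetic_config(n_proteins = 30L, n_pos_pairs = 40L,
                               n_neg_pairs = 40L, n_modules = 6L,
                               latent_dim = 6L, seed = 77L)
  te <- simulate_ppi_data(test_cfg)
  cfg <- pipeline_config(out_dim = 5, k_nn = 3)
  res <- independent_test(d$pssms, d$pairs, te$pssms, te$pairs, cfg, seed = 5)
  flipped_pairs <- te$pairs
  flipped_pairs$label <- 1L - flipped_pairs$label
  res_f <- independent_test(d$pssms, d$pairs, te$pssms, flipped_pairs, cfg,
                            seed = 5)
  expect_equal(res_f$metrics[["accuracy"]], 1 - res$metrics[["accuracy"]],
               tolerance = 1e-12)
  # scores never depend on test labels
  expect_identical(res$scores, res_f$scores)
})

test_that("a trained model transfers signal to unseen proteins from the same world", {
  # cross-dataset protocol: fresh proteins drawn from the training world;
  # transfer is well above chance but below pair-level CV (new proteins,
  # not just new pairs) — see the methods vignette on this gap
  tr <- simulate_ppi_data(synthetic_config(seed = 1))
  te <- simulate_ppi_data(synthetic_config(seed = 1001), world_seed = 1,
                          id_prefix = "tst")
  res <- independent_test(tr$pssms, tr$pairs, te$pssms, te$pairs,
                          pipeline_config(out_dim = 20), seed = 1)
  expect_gt(res$auc, 0.75)
  expect_gt(res$metrics[["accuracy"]], 0.6)
})

test_that("self-evaluation on the training fixture equals training metrics", {
  d <- small_benchmark()
  cfg <- pipeline_config(out_dim = 5, k_nn = 3)
  res1 <- independent_test(d$pssms, d$pairs, d$pssms, d$pairs, cfg, seed = 6)
  res2 <- independent_test(d$pssms, d$pairs, d$pssms, d$pairs, cfg, seed = 6)
  expect_identical(res1$metrics, res2$metrics)
  expect_gte(res1$metrics[["accuracy"]], 0.99)  # unpruned trees fit train data
})
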