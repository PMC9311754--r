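test_that("feature partitions have the stated sizes and cover all indices", {
  set.seed(1)
  p <- partition_features(10, 5)
  expect_identical(unname(lengths(p)), rep(2L, 5))
  expect_setequal(unlist(p), 1:10)
  q <- partition_features(7, 3)
  expect_identical(unname(lengths(q)), c(3L, 2L, 2L))
  expect_setequal(unlist(q), 1:7)
  set.seed(99); a <- partition_features(12, 4)
  set.seed(99); b <- partition_features(12, 4)
  expect_identical(a, b)
  expect_error(partition_features(3, 4), "K")
})

test_that("rotation matrices are orthogonal and norm-preserving", {
  set.seed(2)
  S <- matrix(rnorm(40 * 12), 40)
  for (rep in 1:10) {
    subsets <- partition_features(12, sample(2:5, 1))
    rot <- build_rotation_matrix(S, subsets)
    expect_lte(max(abs(crossprod(rot$F) - diag(12))), 1e-8)
    norms_before <- sqrt(rowSums(S^2))
    norms_after <- sqrt(rowSums((S %*% rot$F)^2))
    expect_equal(norms_after, norms_before, tolerance = 1e-8)
  }
})

test_that("axis-aligned blocks rotate to a signed permutation of the axes", {
  set.seed(3)
  # subset columns already on coordinate axes with unequal variances
  S <- cbind(rnorm(600, sd = 3), rnorm(600, sd = 0.5),
             rnorm(600, sd = 2), rnorm(600, sd = 1))
  rot <- build_rotation_matrix(S, list(c(1L, 2L), c(3L, 4L)))
  blk <- abs(rot$F[1:2, 1:2])
  expect_equal(blk, diag(2), tolerance = 0.05)
})

test_that("zero-variance subsets fall back to identity blocks", {
  S <- cbind(rnorm(20), rep(1, 20), rep(2, 20))
  rot <- build_rotation_matrix(S, list(1L, c(2L, 3L)))
  expect_identical(rot$F[2:3, 2:3], diag(2))
})

test_that("the ensemble separates two well-separated blobs perfectly", {
  set.seed(4)
  X <- rbind(matrix(rnorm(100 * 4), 100), matrix(rnorm(100 * 4, mean = 5), 100))
  y <- rep(c(0L, 1L), each = 100)
  model <- rotation_forest(X, y, K = 2, L = 5, seed = 4)
  expect_identical(predict(model, X), y)
})

test_that("a one-tree forest equals its single rotated tree", {
  set.seed(5)
  X <- matrix(rnorm(60 * 6), 60)
  y <- as.integer(X[, 1] + rnorm(60, sd = 0.3) > 0)
  model <- rotation_forest(X, y, K = 3, L = 1, seed = 5)
  mem <- model$members[[1]]
  df <- as.data.frame(X %*% mem$rotation$F)
  names(df) <- paste0("f", 1:6)
  expect_equal(predict_proba(model, X),
               predict(mem$tree, df, type = "prob")[, c("0", "1")],
               tolerance = 0, ignore_attr = TRUE)
})

test_that("flipping training labels flips the predictions", {
  set.seed(6)
  X <- matrix(rnorm(80 * 4), 80)
  y <- as.integer(X[, 2] > 0.2)
  m1 <- rotation_forest(X, y, seed = 7, K = 2)
  m2 <- rotation_forest(X, 1L - y, seed = 7, K = 2)
  expect_identical(predict(m1, X), 1L - predict(m2, X))
})

test_that("posteriors are normalized and consistent with label predictions", {
  set.seed(8)
  X <- matrix(rnorm(50 * 4), 50)
  y <- as.integer(rowSums(X) > 0)
  model <- rotation_forest(X, y, K = 2, L = 5, seed = 8)
  Xq <- matrix(rnorm(30 * 4), 30)
  p <- predict_proba(model, Xq)
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-12)
  expect_identical(predict(model, Xq), as.integer(p[, "1"] > 0.5))
})

test_that("an exact posterior tie is called class 0", {
  # two identical points with conflicting labels cannot be split: the
  # single leaf carries posterior (0.5, 0.5)
  X <- rbind(c(1, 1), c(1, 1), c(4, 4), c(4, 4))
  y <- c(0L, 1L, 0L, 1L)
  model <- rotation_forest(X, y, K = 1, L = 1, seed = 1)
  p <- predict_proba(model, X)
  expect_equal(p[, "1"], rep(0.5, 4), tolerance = 0, ignore_attr = TRUE)
  expect_identical(predict(model, X), rep(0L, 4))
})

test_that("fits are bit-reproducible from the seed", {
  set.seed(9)
  X <- matrix(rnorm(60 * 6), 60)
  y <- as.integer(X[, 1] > 0)
  Xq <- matrix(rnorm(20 * 6), 20)
  m1 <- rotation_forest(X, y, seed = 42)
  m2 <- rotation_forest(X, y, seed = 42)
  expect_identical(predict_proba(m1, Xq), predict_proba(m2, Xq))
  expect_identical(lapply(m1$members, function(m) m$rotation$F),
                   lapply(m2$members, function(m) m$rotation$F))
})

test_that("single-class training data is rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(rotation_forest(X, rep(1L, 10)), "both classes")
})

test_that("dimension mismatches at prediction are caught", {
  set.seed(10)
  X <- matrix(rnorm(40), 20)
  model <- rotation_forest(X, rep_len(0:1, 20), K = 2, seed = 1)
  expect_error(predict_proba(model, matrix(0, 2, 3)), "features")
})
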