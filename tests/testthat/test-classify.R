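test_that("one-vs-rest label mapping pools the two negative codes", {
  expect_equal(makeBinaryTask(c(1L, 2L, 3L, 2L), 2L), c(0L, 1L, 0L, 1L))
  expect_equal(makeBinaryTask(c(1L, 2L, 3L, 2L), 3L), c(0L, 0L, 1L, 0L))
  expect_error(makeBinaryTask(c(1L, 1L), 2L), "absent")
  expect_error(makeBinaryTask(c(1L, 4L), 2L), "labels")
  expect_error(makeBinaryTask(c(1L, 2L), 5), "positive")
})

test_that("KNN votes among Euclidean nearest neighbours", {
  X <- rbind(c(0, 0), c(1, 1))
  m <- trainKnn(X, c(0L, 1L), k = 1)
  expect_equal(predictKnn(m, rbind(c(0.1, 0))), 0L)
  expect_equal(predictKnn(m, X[2, , drop = FALSE]), 1L)

  # k = n -> global majority regardless of query
  X3 <- rbind(c(0, 0), c(1, 1), c(2, 2))
  m3 <- trainKnn(X3, c(1L, 1L, 0L), k = 3)
  expect_equal(predictKnn(m3, rbind(c(100, 100))), 1L)

  # vote ties go to the negative class
  m2 <- trainKnn(X, c(0L, 1L), k = 2)
  expect_equal(predictKnn(m2, rbind(c(0.5, 0.5))), 0L)

  expect_error(trainKnn(X, c(0L, 1L), k = 3), "exceeds")
})

test_that("KNN matches the established implementation off tie cases", {
  skip_if_not_installed("class")
  set.seed(10)
  X <- matrix(rnorm(60 * 4), 60)
  y <- rep(c(0L, 1L), 30)
  Q <- matrix(rnorm(25 * 4), 25)
  mine <- predictKnn(trainKnn(X, y, k = 5), Q)
  ref <- as.integer(as.character(class::knn(X, Q, factor(y), k = 5)))
  expect_equal(mine, ref)
})

test_that("LDA places the boundary at the midpoint of equal classes", {
  x <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  m <- trainLda(x, y)
  expect_equal(predictLda(m, rbind(0.1)), 1L)
  expect_equal(predictLda(m, rbind(-0.1)), 0L)

  # duplicated feature column exercises the ridge fallback, no crash
  xd <- cbind(x, x)
  md <- trainLda(xd, y)
  expect_true(md$ridge)
  expect_equal(predictLda(md, rbind(c(0.5, 0.5))), 1L)

  expect_error(trainLda(x, c(0L, rep(1L, 5))), "at least 2")
})

test_that("LDA separates Gaussian blobs and agrees with MASS", {
  set.seed(20)
  X <- rbind(matrix(rnorm(100, -2), 50, 2), matrix(rnorm(100, 2), 50, 2))
  y <- rep(c(0L, 1L), each = 50)
  m <- trainLda(X, y)
  expect_gte(mean(predictLda(m, X) == y), 0.99)

  skip_if_not_installed("MASS")
  ref <- MASS::lda(X, grouping = factor(y))
  ref_pred <- as.integer(as.character(predict(ref, X)$class))
  expect_gte(mean(predictLda(m, X) == ref_pred), 0.99)
})

test_that("boosted learner separates blobs and fails on shuffled labels", {
  skip_if_not_installed("xgboost")
  tab <- separableTable(n_per = 25, delta = 3, seed = 2)
  spec <- learnerSpec("gbm_xtreme", rounds = 50)
  cv <- crossValidate(tab, spec, positive = 2L, k_folds = 5, seed = 1)
  expect_gte(cv$mean_accuracy, 0.95)

  # label permutation: accuracy within the binomial 95% CI of 0.5
  tab_perm <- tab
  tab_perm$label <- withSeed(5, sample(tab$label))
  cvp <- crossValidate(tab_perm, spec, positive = 2L, k_folds = 5, seed = 1)
  n <- nrow(tab_perm)
  expect_lt(abs(cvp$mean_accuracy - 0.5), 1.96 * sqrt(0.25 / n) + 0.05)

  # monotone single feature: at least as good as the best single
  # threshold found by exhaustive search
  tab1 <- separableTable(n_per = 25, delta = 1.2, seed = 3)[, 1:5]
  thr_acc <- max(vapply(sort(tab1$f1), function(th)
    max(mean((tab1$f1 > th) == (tab1$label == 2L)),
        mean((tab1$f1 <= th) == (tab1$label == 2L))), numeric(1)))
  m <- trainBoosted(as.matrix(tab1[, "f1", drop = FALSE]),
                    as.integer(tab1$label == 2L), "gbm_xtreme", seed = 1)
  train_acc <- mean(predictBoosted(
    m, as.matrix(tab1[, "f1", drop = FALSE])) == (tab1$label == 2L))
  expect_gte(train_acc, thr_acc - 1e-9)
})

test_that("the LightGBM backend reports itself as unavailable", {
  skip_if(requireNamespace("lightgbm", quietly = TRUE),
          "lightgbm happens to be installed")
  expect_error(trainBoosted(matrix(rnorm(20), 10), rep(0:1, 5),
                            backend = "gbm_light"),
               "lightgbm")
})

test_that("cross-validation folds are stratified, disjoint and seeded", {
  tab <- separableTable(n_per = 20, seed = 4)
  spec <- learnerSpec("knn", k = 3)

  r1 <- crossValidate(tab, spec, positive = 2L, k_folds = 5, seed = 9)
  r2 <- crossValidate(tab, spec, positive = 2L, k_folds = 5, seed = 9)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$confusions, r2$confusions)

  # confusion matrices partition all rows
  expect_equal(sum(vapply(r1$confusions, sum, numeric(1))), nrow(tab))
  # stratification: each fold sees 4 positives and 4 negatives
  for (cm in r1$confusions) {
    expect_equal(sum(cm[, "1"]), 4)
    expect_equal(sum(cm[, "0"]), 4)
  }

  # perfectly separable with knn k = 1 -> accuracy 1
  sep <- separableTable(n_per = 20, delta = 10, seed = 6, sd = 0.1)
  r <- crossValidate(sep, learnerSpec("knn", k = 1), positive = 2L,
                     k_folds = 5, seed = 2)
  expect_equal(r$mean_accuracy, 1)

  # constant features -> majority-class proportion in every fold
  cons <- tab
  cons$f1 <- 1; cons$f2 <- 1
  cons$label <- rep(c(1L, 1L, 1L, 2L), 10)
  rc <- crossValidate(cons, learnerSpec("knn", k = 5), positive = 2L,
                      k_folds = 5, seed = 3)
  expect_equal(rc$fold_accuracy, rep(0.75, 5))

  expect_error(crossValidate(tab[c(1:3, 21:23), ], spec, positive = 2L,
                             k_folds = 5),
               "k_folds")
})

test_that("fold class ratios stay within one of proportional", {
  tab <- separableTable(n_per = 23, seed = 12)  # 46 rows, uneven folds
  y <- makeBinaryTask(tab$label, 2L)
  fold <- integer(length(y))
  withSeed(4, for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(5), length(idx))
  })
  for (f in 1:5) {
    expect_lt(abs(sum(y[fold == f] == 1) - 23 / 5), 1)
    expect_lt(abs(sum(y[fold == f] == 0) - 23 / 5), 1)
  }
})
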