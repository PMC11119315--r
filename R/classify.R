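#' @include fused_features.R
NULL

#' Binarize activity labels for a one-vs-rest task
#'
#' The chosen imagery class becomes the positive class (1); baseline and
#' the other imagery class together form the negative class (0). Two such
#' tasks — mental drawing (positive = 2) and spatial navigation (positive
#' = 3) — are run by independent classifiers.
#'
#' @param labels integer vector with codes in \{1, 2, 3\}
#' @param positive positive class code, 2 or 3
#' @return integer 0/1 vector
#' @export
makeBinaryTask <- function(labels, positive) {
  stopifnot(positive %in% c(2L, 3L))
  if (!all(labels %in% c(1L, 2L, 3L)))
    stop("labels must be 1, 2 or 3")
  if (!any(labels == positive))
    stop("positive class ", positive, " is absent from the labels")
  as.integer(labels == positive)
}

#' Specify a learner
#'
#' @param kind \code{"knn"}, \code{"lda"}, \code{"gbm_light"} or
#'   \code{"gbm_xtreme"}
#' @param k neighbours for KNN (Euclidean metric, uniform weights)
#' @param rounds boosting rounds for the gradient-boosted backends
#' @return list of class \code{"LearnerSpec"}
#' @export
learnerSpec <- function(kind = c("knn", "lda", "gbm_light", "gbm_xtreme"),
                        k = 10L, rounds = 50L) {
  kind <- match.arg(kind)
  stopifnot(k >= 1L, rounds >= 1L)
  structure(list(kind = kind, k = as.integer(k),
                 rounds = as.integer(rounds),
                 standardize = kind %in% c("knn", "lda")),
            class = "LearnerSpec")
}

#' K-nearest-neighbour classifier (Euclidean, uniform weights)
#'
#' Majority vote among the k nearest training rows. Distance ties are
#' broken by training-row order; vote ties go to the negative class.
#'
#' @param X numeric training matrix (rows = samples)
#' @param y integer 0/1 labels
#' @param k neighbour count, \code{k <= nrow(X)}
#' @return model object for [predictKnn()]
#' @export
trainKnn <- function(X, y, k = 10L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (k > nrow(X))
    stop("k = ", k, " exceeds the training size ", nrow(X))
  structure(list(X = X, y = as.integer(y), k = as.integer(k)),
            class = "KnnModel")
}

#' @rdname trainKnn
#' @param model a fitted \code{"KnnModel"}
#' @param Xq numeric query matrix
#' @return integer 0/1 predictions
#' @export
predictKnn <- function(model, Xq) {
  Xq <- rbind(Xq)
  apply(Xq, 1L, function(q) {
    d2 <- rowSums((model$X - rep(q, each = nrow(model$X)))^2)
    nn <- order(d2, seq_along(d2))[seq_len(model$k)]  # ties: row order
    pos <- sum(model$y[nn] == 1L)
    as.integer(pos > model$k - pos)  # vote tie -> negative class
  })
}

#' Linear discriminant classifier with shared covariance
#'
#' Gaussian discriminant with pooled within-class covariance and empirical
#' priors; the decision takes the larger discriminant score. A singular or
#' ill-conditioned pooled covariance falls back to a ridge
#' (\code{lambda = 1e-6 * trace/dim}).
#'
#' @param X numeric training matrix
#' @param y integer 0/1 labels, each class with >= 2 rows
#' @return model object for [predictLda()]
#' @export
trainLda <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need both classes in the training data")
  if (any(table(y) < 2L)) stop("each class needs at least 2 training rows")
  p <- ncol(X)
  mus <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  S <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    Xc <- X[y == classes[ci], , drop = FALSE]
    Xc <- sweep(Xc, 2L, mus[ci, ])
    S <- S + crossprod(Xc)
  }
  S <- S / (nrow(X) - length(classes))
  ridge_used <- FALSE
  Sinv <- tryCatch({
    if (rcond(S) < 1e-10) stop("ill-conditioned")
    solve(S)
  }, error = function(e) {
    ridge_used <<- TRUE
    solve(S + diag(1e-6 * sum(diag(S)) / p, p))
  })
  priors <- as.numeric(table(factor(y, classes))) / length(y)
  structure(list(classes = classes, mus = mus, Sinv = Sinv,
                 priors = priors, ridge = ridge_used),
            class = "LdaModel")
}

#' @rdname trainLda
#' @param model a fitted \code{"LdaModel"}
#' @param Xq numeric query matrix
#' @return integer predicted labels
#' @export
predictLda <- function(model, Xq) {
  Xq <- rbind(Xq)
  scores <- vapply(seq_along(model$classes), function(ci) {
    mu <- model$mus[ci, ]
    drop(Xq %*% model$Sinv %*% mu) -
      0.5 * drop(t(mu) %*% model$Sinv %*% mu) + log(model$priors[ci])
  }, numeric(nrow(Xq)))
  scores <- rbind(scores)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Gradient-boosted tree classifier behind a uniform interface
#'
#' \code{"gbm_xtreme"} uses the xgboost backend (binary logistic, 50
#' rounds by default, single-threaded, seeded). \code{"gbm_light"} raises
#' an informative error when the LightGBM backend is not installed.
#'
#' @param X numeric training matrix
#' @param y integer 0/1 labels
#' @param backend \code{"gbm_xtreme"} or \code{"gbm_light"}
#' @param rounds boosting rounds
#' @param seed RNG seed for the backend
#' @return model object for [predictBoosted()]
#' @export
trainBoosted <- function(X, y, backend = c("gbm_xtreme", "gbm_light"),
                         rounds = 50L, seed = 1L) {
  backend <- match.arg(backend)
  if (backend == "gbm_light") {
    if (!requireNamespace("lightgbm", quietly = TRUE))
      stop("the 'gbm_light' backend needs the optional package 'lightgbm', ",
           "which is not installed; use backend = 'gbm_xtreme' or install it")
    booster <- lightgbm::lightgbm(
      data = X, label = y, nrounds = rounds, verbose = -1L,
      params = list(objective = "binary", seed = seed, num_threads = 1L))
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("the 'gbm_xtreme' backend needs the optional package 'xgboost'")
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
    booster <- withSeed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L,
                    nthread = 1L, seed = seed),
      data = dtrain, nrounds = rounds, verbose = 0))
  }
  structure(list(backend = backend, booster = booster), class = "GbmModel")
}

#' @rdname trainBoosted
#' @param model a fitted \code{"GbmModel"}
#' @param Xq numeric query matrix
#' @return integer 0/1 predictions (probability threshold 0.5)
#' @export
predictBoosted <- function(model, Xq) {
  p <- if (model$backend == "gbm_light") predict(model$booster, Xq)
       else predict(model$booster, xgboost::xgb.DMatrix(Xq))
  as.integer(p > 0.5)
}

# Uniform train/predict closure for a LearnerSpec.
makeLearner <- function(spec, seed = 1L) {
  switch(spec$kind,
    knn = list(train = function(X, y) trainKnn(X, y, spec$k),
               predict = predictKnn),
    lda = list(train = trainLda, predict = predictLda),
    gbm_light = list(
      train = function(X, y)
        trainBoosted(X, y, "gbm_light", spec$rounds, seed),
      predict = predictBoosted),
    gbm_xtreme = list(
      train = function(X, y)
        trainBoosted(X, y, "gbm_xtreme", spec$rounds, seed),
      predict = predictBoosted))
}

# Columns of a feature table that hold features (not metadata).
featureColumns <- function(table) {
  setdiff(names(table), c("epoch", "label", "stream", "feature_set"))
}

#' Stratified k-fold cross-validation of a one-vs-rest task
#'
#' Rows are split into seeded stratified folds (per-fold class counts
#' within one of proportional), the learner is trained on each training
#' split and scored on the held-out fold. KNN and LDA features are
#' standardized with train-fold mean/sd; trees consume raw features.
#'
#' @param table feature data.frame with a \code{label} column (codes
#'   1/2/3) and feature columns; see [classicalFeatures()],
#'   [featurizeFused()]
#' @param spec a [learnerSpec()]
#' @param positive positive class code (2 = mental drawing, 3 = spatial
#'   navigation)
#' @param k_folds number of folds; every class must have at least
#'   \code{k_folds} rows
#' @param seed fold-assignment (and learner) seed
#' @return list of class \code{"CvReport"}: \code{fold_accuracy},
#'   \code{mean_accuracy}, \code{confusions} (list of 2x2 matrices,
#'   predicted x actual), \code{task}, \code{seed}, \code{learner}
#' @export
crossValidate <- function(table, spec, positive, k_folds = 5L, seed = 1L) {
  y <- makeBinaryTask(table$label, positive)
  X <- as.matrix(table[, featureColumns(table), drop = FALSE])
  storage.mode(X) <- "double"
  if (any(table(y) < k_folds))
    stop("every class needs at least k_folds = ", k_folds, " rows")

  fold <- integer(length(y))
  withSeed(seed, for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  })

  learner <- makeLearner(spec, seed = seed)
  acc <- numeric(k_folds)
  confusions <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (spec$standardize) {
      ctr <- colMeans(Xtr)
      sds <- apply(Xtr, 2L, stats::sd)
      sds[sds == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, sds, "/")
      Xte <- sweep(sweep(Xte, 2L, ctr), 2L, sds, "/")
    }
    model <- learner$train(Xtr, y[tr])
    pred <- learner$predict(model, Xte)
    acc[f] <- mean(pred == y[te])
    confusions[[f]] <- table(predicted = factor(pred, 0:1),
                             actual = factor(y[te], 0:1))
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusions = confusions,
                 task = if (positive == 2L) "MD" else "SN",
                 seed = as.integer(seed), learner = spec$kind),
            class = "CvReport")
}

#' @export
print.CvReport <- function(x, ...) {
  cat("CvReport [", x$task, ", ", x$learner, "]: mean accuracy ",
      sprintf("%.3f", x$mean_accuracy), " over ", length(x$fold_accuracy),
      " folds (", paste(sprintf("%.2f", x$fold_accuracy), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
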