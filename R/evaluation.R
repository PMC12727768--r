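#' Stratified k-fold split
#'
#' Partitions `1..n` into `k` disjoint, exhaustive folds whose sizes differ
#' by at most one, stratified by `labels` so every fold mirrors the class
#' mix. A class with fewer than `k` members triggers a fall back to an
#' unstratified split with a warning. Deterministic for a given seed.
#'
#' @param n number of observations.
#' @param k number of folds (default 10).
#' @param labels optional per-observation class labels for stratification.
#' @param seed RNG seed.
#' @return List of `k` integer index vectors.
#' @export
kfold_split <- function(n, k = 10, labels = NULL, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  with_seed(seed, {
    if (!is.null(labels)) {
      stopifnot(length(labels) == n)
      if (min(table(labels)) < k) {
        warning("a class has fewer than k members; using unstratified folds")
        labels <- NULL
      }
    }
    folds <- vector("list", k)
    if (is.null(labels)) {
      fold_of <- sample(rep_len(seq_len(k), n))
    } else {
      fold_of <- integer(n)
      sizes <- integer(k)
      for (cl in sample(unique(labels))) {
        idx <- sample(which(labels == cl))
        nc <- length(idx)
        base <- nc %/% k
        r <- nc %% k
        # remainders go to the currently smallest folds, keeping overall
        # fold sizes within one of each other
        alloc <- rep(base, k)
        if (r > 0) {
          smallest <- order(sizes, sample.int(k))[seq_len(r)]
          alloc[smallest] <- alloc[smallest] + 1L
        }
        fold_of[idx] <- rep(seq_len(k), times = alloc)
        sizes <- sizes + alloc
      }
    }
    for (j in seq_len(k)) folds[[j]] <- which(fold_of == j)
    folds
  })
}

#' Accuracy from a confusion matrix
#'
#' Correct predictions (the trace) over all tested samples.
#'
#' @param confusion square numeric matrix of counts, true classes in rows.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation over the mean, times 100; used to compare the
#' spread of per-subject accuracies across datasets.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return Percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  stats::sd(values) / m * 100
}

# z-score scaling fit on train, applied to both (zero-variance cols pass
# through centered only)
fit_apply_scaling <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

# inner-CV selection of KNN's K on the training fold only
select_knn_k <- function(xtr, ytr, grid = c(1, 3, 5, 7, 9, 11), seed = 1L) {
  k_inner <- min(5L, min(table(ytr)))
  if (k_inner < 2L) return(grid[1])
  folds <- kfold_split(length(ytr), k_inner, labels = ytr, seed = seed)
  acc <- vapply(grid, function(kk) {
    correct <- 0L
    for (f in folds) {
      pred <- class::knn(xtr[-f, , drop = FALSE], xtr[f, , drop = FALSE],
                         ytr[-f], k = kk)
      correct <- correct + sum(pred == ytr[f])
    }
    correct / length(ytr)
  }, numeric(1))
  grid[which.max(acc)]
}

# inner-CV grid for the decision tree (deterministic small grid)
select_dt_params <- function(xtr, ytr, seed = 1L) {
  grid <- expand.grid(maxdepth = c(5, 10, 30), minsplit = c(5, 20))
  k_inner <- min(3L, min(table(ytr)))
  if (k_inner < 2L) return(grid[1, ])
  folds <- kfold_split(length(ytr), k_inner, labels = ytr, seed = seed)
  df <- data.frame(xtr)
  df$.y <- ytr
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L
    for (f in folds) {
      fit <- rpart::rpart(.y ~ ., data = df[-f, ], method = "class",
                          control = rpart::rpart.control(
                            maxdepth = grid$maxdepth[g],
                            minsplit = grid$minsplit[g], cp = 0.001,
                            xval = 0))
      pred <- predict(fit, df[f, ], type = "class")
      correct <- correct + sum(pred == ytr[f])
    }
    correct / length(ytr)
  }, numeric(1))
  grid[which.max(acc), ]
}

train_predict <- function(classifier, xtr, ytr, xte, params, seed) {
  switch(classifier,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial",
                        cost = params$cost %||% 1, scale = FALSE)
      predict(fit, xte)
    },
    knn = {
      kk <- params$k %||% select_knn_k(xtr, ytr, seed = seed)
      class::knn(xtr, xte, ytr, k = kk)
    },
    dt = {
      pp <- if (!is.null(params$maxdepth))
        data.frame(maxdepth = params$maxdepth,
                   minsplit = params$minsplit %||% 20)
      else select_dt_params(xtr, ytr, seed = seed)
      df <- data.frame(xtr); df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = pp$maxdepth, minsplit = pp$minsplit,
                            cp = 0.001, xval = 0))
      predict(fit, data.frame(xte), type = "class")
    },
    rf = {
      fit <- with_seed(seed, randomForest::randomForest(
        xtr, ytr, ntree = params$n_trees %||% 146))
      predict(fit, xte)
    },
    stop("unknown classifier: ", classifier))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' k-fold cross-validated classification
#'
#' Stratified k-fold cross-validation of a [feature_matrix()] with one of
#' the four benchmark classifiers: `"svm"` (Gaussian kernel, box constraint
#' 1), `"knn"` (K chosen by inner CV over 1,3,...,11 on the training folds),
#' `"dt"` (rpart with a small depth/min-split grid chosen by inner CV), or
#' `"rf"` (random forest, 146 trees). Features are z-scored with statistics
#' fit on the training folds only. Rest segments (label 0) are excluded by
#' default.
#'
#' @param features a [feature_matrix()].
#' @param classifier `"rf"`, `"svm"`, `"knn"` or `"dt"`.
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling folds and any stochastic trainer.
#' @param drop_rest exclude label-0 rows before splitting (default `TRUE`).
#' @param params classifier-specific overrides: `cost` (svm), `k` (knn),
#'   `maxdepth`/`minsplit` (dt), `n_trees` (rf).
#' @return An object of class `cv_result`: `fold_accuracies`,
#'   `mean_accuracy`, `std_accuracy`, `confusion` (true classes in rows,
#'   aggregated over folds), `classifier`, `seed`.
#' @export
cross_validate <- function(features, classifier = c("rf", "svm", "knn", "dt"),
                           k = 10, seed = 1L, drop_rest = TRUE,
                           params = list()) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$values
  y <- features$row_labels
  if (drop_rest) {
    keep <- y != 0L
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (length(y) < k) stop("fewer observations than folds")
  yf <- factor(y, levels = classes)
  folds <- kfold_split(length(y), k, labels = y, seed = seed)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, pred = classes))
  fold_acc <- numeric(k)
  for (j in seq_len(k)) {
    te <- folds[[j]]
    sc <- fit_apply_scaling(X[-te, , drop = FALSE], X[te, , drop = FALSE])
    pred <- train_predict(classifier, sc$train, yf[-te], sc$test, params,
                          seed = seed + j)
    tab <- table(factor(yf[te], levels = classes),
                 factor(pred, levels = classes))
    conf <- conf + as.matrix(tab)
    fold_acc[j] <- mean(pred == yf[te])
  }
  structure(
    list(fold_accuracies = fold_acc, mean_accuracy = mean(fold_acc),
         std_accuracy = stats::sd(fold_acc), confusion = conf,
         classifier = classifier, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold: accuracy %.1f%% +/- %.1f%%\n",
              x$classifier, length(x$fold_accuracies),
              100 * x$mean_accuracy, 100 * x$std_accuracy))
  invisible(x)
}

#' Mode-count sweep of the VMD-SVD pipeline
#'
#' For each K in `K_values`, regenerates VMD-SVD features from the raw
#' recording, runs cross-validation, and reports the feature dimensionality
#' `M = channels * K`, mean and std accuracy, and the feature-extraction
#' wall time (informational only).
#'
#' @param rec an [emg_recording()] with labels.
#' @param K_values integer mode counts (default 2, 4, 6, 8, 10, 12).
#' @param classifier,k,seed,params passed to [cross_validate()].
#' @param window_ms,overlap_frac,... segmentation and VMD settings passed
#'   to [extract_vmd_svd()].
#' @return A data.frame with one row per K: `K`, `M`, `mean_accuracy`,
#'   `std_accuracy`, `extract_seconds`.
#' @export
vmf_sweep <- function(rec, K_values = c(2, 4, 6, 8, 10, 12),
                      classifier = "rf", k = 10, seed = 1L,
                      window_ms = 250, overlap_frac = 0.10, params = list(),
                      ...) {
  stopifnot(inherits(rec, "emg_recording"), length(K_values) >= 1)
  rows <- lapply(K_values, function(K) {
    t0 <- proc.time()[["elapsed"]]
    fm <- extract_vmd_svd(rec, K = K, window_ms = window_ms,
                          overlap_frac = overlap_frac, ...)
    dt <- proc.time()[["elapsed"]] - t0
    cv <- cross_validate(fm, classifier, k = k, seed = seed,
                         params = params)
    data.frame(K = K, M = ncol(fm$values),
               mean_accuracy = cv$mean_accuracy,
               std_accuracy = cv$std_accuracy,
               extract_seconds = dt)
  })
  do.call(rbind, rows)
}
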