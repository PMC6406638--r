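# Novice/expert classification: five classifiers, stratified CV, and the
# wrapper sequential forward search.

CLASSIFIERS <- c("lda", "knn", "nb", "svm", "tree")

# Stratified fold assignment: within each class, shuffle and deal round-robin.
stratified_folds <- function(y, k, seed) {
  if (any(table(y) < k)) {
    stop("stratification error: a class has fewer observations than folds", call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- (sample(seq_along(idx)) %% k) + 1L
    }
  })
  folds
}

# Fit on (Xtr, ytr) and predict Xte. Features are z-scored with training-fold
# statistics (constant columns pinned to 0) so distance- and kernel-based
# classifiers see comparable scales. Degenerate fits fall back to the
# training majority class.
fit_predict <- function(classifier, Xtr, ytr, Xte, knn_k = 3L) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Zte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  majority <- names(which.max(table(ytr)))
  pred <- tryCatch(switch(
    classifier,
    lda = {
      keep <- apply(Ztr, 2, function(v) any(tapply(v, ytr, stats::sd) > 0))
      if (!any(keep)) stop("no usable feature")
      fit <- MASS::lda(Ztr[, keep, drop = FALSE], grouping = ytr)
      as.character(stats::predict(fit, Zte[, keep, drop = FALSE])$class)
    },
    knn = as.character(class::knn(Ztr, Zte, cl = ytr, k = knn_k)),
    nb = {
      fit <- e1071::naiveBayes(Ztr, ytr)
      as.character(stats::predict(fit, Zte))
    },
    svm = {
      fit <- e1071::svm(Ztr, ytr, kernel = "radial")
      as.character(stats::predict(fit, Zte))
    },
    tree = {
      d <- data.frame(Ztr, y = ytr, check.names = TRUE)
      fit <- rpart::rpart(y ~ ., data = d, method = "class")
      nd <- data.frame(Zte, check.names = TRUE)
      names(nd) <- setdiff(names(d), "y")
      as.character(stats::predict(fit, nd, type = "class"))
    },
    stop(sprintf("unknown classifier '%s'", classifier), call. = FALSE)
  ), error = function(e) rep(majority, nrow(Xte)))
  factor(pred, levels = levels(ytr))
}

cv_predictions <- function(X, y, cols, folds, classifier, knn_k = 3L) {
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    pred[te] <- fit_predict(classifier,
                            X[!te, cols, drop = FALSE], y[!te],
                            X[te, cols, drop = FALSE], knn_k = knn_k)
  }
  pred
}

#' Sequential forward feature selection (wrapper)
#'
#' Greedy forward search: starting from the empty set, each step adds the
#' feature whose inclusion maximizes stratified k-fold cross-validated
#' accuracy of the wrapped classifier; ties break to the lowest feature
#' index. The search stops when no candidate strictly improves the accuracy
#' or when `max_features` are selected. Fold assignment is fixed once from
#' `seed`, so every candidate is scored on identical folds.
#'
#' @param X numeric feature matrix (windows x features).
#' @param y factor of class labels (2 classes).
#' @param classifier one of `"lda"`, `"knn"`, `"nb"`, `"svm"`, `"tree"`.
#' @param cv_folds number of folds. Default 5.
#' @param max_features maximum number of features to select. Default all.
#' @param seed integer seed (fold assignment).
#' @param knn_k neighbours for `"knn"`. Default 3.
#' @return an `sfs_result`: list with `selected` (feature indices, in
#'   selection order), `accuracy_trace` (CV accuracy after each addition),
#'   `elapsed` (seconds), `classifier`.
#' @export
sequential_forward_search <- function(X, y, classifier = "knn", cv_folds = 5L,
                                      max_features = ncol(X), seed = 1L,
                                      knn_k = 3L) {
  classifier <- match.arg(classifier, CLASSIFIERS)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("labels contain a single class", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  folds <- stratified_folds(y, cv_folds, seed)
  selected <- integer(0)
  trace <- numeric(0)
  best <- -Inf
  while (length(selected) < max_features) {
    candidates <- setdiff(seq_len(ncol(X)), selected)
    acc <- vapply(candidates, function(j) {
      mean(cv_predictions(X, y, c(selected, j), folds, classifier, knn_k) == y)
    }, numeric(1))
    j_best <- candidates[which.max(acc)]  # first max = lowest index on ties
    if (max(acc) <= best) break
    best <- max(acc)
    selected <- c(selected, j_best)
    trace <- c(trace, best)
  }
  structure(list(selected = selected, accuracy_trace = trace,
                 elapsed = proc.time()[["elapsed"]] - t0,
                 classifier = classifier),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %s: %d feature(s) selected, CV accuracy %.3f (%.1f s)\n",
              x$classifier, length(x$selected),
              if (length(x$accuracy_trace)) max(x$accuracy_trace) else NA,
              x$elapsed))
  cat("  indices:", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

#' Cross-validated evaluation of a feature subset
#'
#' Stratified k-fold cross-validation with predictions pooled over folds.
#' The novice label is the positive class, so sensitivity is the novice
#' recall and specificity the expert recall. The mean squared error is the
#' mean squared 0/1 label error, which for hard predictions equals
#' `1 - accuracy`.
#'
#' @inheritParams sequential_forward_search
#' @param feature_subset non-empty integer vector of feature columns.
#' @param positive positive class label. Default `"novice"`.
#' @return an `evaluation_report`: list with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_measure`, `mse`, `selected_features`,
#'   `per_fold` (accuracy per fold), `confusion`.
#' @export
evaluate <- function(X, y, classifier = "knn", feature_subset, cv_folds = 5L,
                     seed = 1L, knn_k = 3L, positive = "novice") {
  classifier <- match.arg(classifier, CLASSIFIERS)
  stopifnot(length(feature_subset) >= 1)
  y <- droplevels(as.factor(y))
  folds <- stratified_folds(y, cv_folds, seed)
  pred <- cv_predictions(X, y, feature_subset, folds, classifier, knn_k)
  pos <- positive
  tp <- sum(pred == pos & y == pos); fn <- sum(pred != pos & y == pos)
  fp <- sum(pred == pos & y != pos); tn <- sum(pred != pos & y != pos)
  acc <- (tp + tn) / length(y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  per_fold <- vapply(sort(unique(folds)), function(f) {
    mean(pred[folds == f] == y[folds == f])
  }, numeric(1))
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, f_measure = f1, mse = mean((pred != y)^2),
                 selected_features = feature_subset, per_fold = per_fold,
                 confusion = table(predicted = pred, truth = y),
                 classifier = classifier),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s on %d feature(s)\n", x$classifier,
              length(x$selected_features)))
  cat(sprintf("  accuracy %.3f | sensitivity %.3f | specificity %.3f | precision %.3f | F %.3f | MSE %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision,
              x$f_measure, x$mse))
  invisible(x)
}
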