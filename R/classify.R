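#' Confusion-derived performance metrics
#'
#' Accuracy, sensitivity, specificity, precision and F-score as
#' percentages. Seizure is the positive class (1), pre-seizure the
#' negative class (0). A zero denominator (e.g. no positives in a fold)
#' yields `NA` for the affected metric.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts.
#' @return named numeric vector `c(ACC, SEN, SPE, PRE, F)` in percent.
#' @export
#' @examples
#' compute_metrics(tp = 50, tn = 40, fp = 10, fn = 0)
compute_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (total < 1) stop("empty confusion matrix")
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- div(tp + tn, total)
  sen <- div(tp, tp + fn)
  spe <- div(tn, fp + tn)
  pre <- div(tp, tp + fp)
  f <- if (!is.na(pre) && !is.na(sen) && pre + sen > 0)
    2 * pre * sen / (pre + sen) else NA_real_
  c(ACC = acc, SEN = sen, SPE = spe, PRE = pre, F = f)
}

# ---- classifier contracts ----------------------------------------------

#' Fit one of the four supported classifiers
#'
#' * `svm`: soft-margin support vector machine, RBF kernel by default.
#' * `knn`: k-nearest neighbours, Euclidean distance, k = 5; distance
#'   ties resolved toward the lower training-row index and vote ties
#'   toward the class of the single nearest neighbour.
#' * `naive_bayes`: Gaussian class-conditional densities per feature,
#'   argmax posterior.
#' * `logistic_regression`: binomial GLM fit by maximum likelihood,
#'   decision at P(seizure) >= 0.5.
#'
#' @param name one of `"svm"`, `"knn"`, `"naive_bayes"`,
#'   `"logistic_regression"`.
#' @param x numeric training matrix (rows = samples).
#' @param y binary labels (0/1 integer, logical, or a 2-level factor).
#' @param kernel SVM kernel (`"radial"`, `"linear"`, `"polynomial"`).
#' @param k number of neighbours for `knn`.
#' @return a fitted model object of class `emdeeg_classifier`.
#' @export
fit_classifier <- function(name = c("svm", "knn", "naive_bayes",
                                    "logistic_regression"),
                           x, y, kernel = "radial", k = 5) {
  name <- match.arg(name)
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  fit <- switch(name,
    svm = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = kernel),
    knn = list(x = x, y = y, k = k),
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    logistic_regression = {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    })
  structure(list(name = name, fit = fit, p = ncol(x)),
            class = "emdeeg_classifier")
}

as_binary_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lv <- sort(unique(as.character(y)))
    if (identical(lv, c("pre_seizure", "seizure")))
      return(as.integer(as.character(y) == "seizure"))
    if (length(lv) > 2) stop("only two-class problems are supported")
    return(as.integer(as.character(y) == lv[length(lv)]))
  }
  as.integer(y != 0)
}

#' Predict class labels (0/1) from a fitted classifier
#' @param object an `emdeeg_classifier`.
#' @param newdata numeric matrix of test samples.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.emdeeg_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(object$name,
    svm = as.integer(as.character(predict(object$fit, newdata))),
    naive_bayes = as.integer(as.character(
      predict(object$fit, as.data.frame(newdata)))),
    logistic_regression = {
      p <- suppressWarnings(
        predict(object$fit, data.frame(newdata), type = "response"))
      as.integer(p >= 0.5)
    },
    knn = knn_predict(object$fit, newdata))
}

knn_predict <- function(fit, newdata) {
  apply(newdata, 1, function(q) {
    d <- sqrt(colSums((t(fit$x) - q)^2))
    nb <- order(d, seq_along(d))[seq_len(min(fit$k, length(d)))]
    votes <- table(fit$y[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) as.integer(top) else fit$y[nb[1]]
  })
}

# ---- cross-validation ---------------------------------------------------

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin into the folds.
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  assign <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validated classification
#'
#' Randomly partitions the feature table into `folds` stratified folds;
#' for each fold, fits the classifier on the remaining folds (features
#' z-scored with training-fold statistics only) and predicts the held-out
#' fold. No separate validation split is used. Per-fold confusion counts
#' and metrics are reported along with their means.
#'
#' @param table a [build_feature_table()] result, or a list with
#'   `values` (matrix) and `labels`.
#' @param classifier one of `"svm"`, `"knn"`, `"naive_bayes"`,
#'   `"logistic_regression"`.
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment.
#' @param ... passed to [fit_classifier()].
#' @return object of class `cv_result`: list with `per_fold`
#'   (data.frame of counts and metrics), `mean_metrics`, `confusion`
#'   (summed counts), `classifier_name`, `folds`, `seed`.
#' @export
cross_validate <- function(table, classifier = c("svm", "knn", "naive_bayes",
                                                 "logistic_regression"),
                           folds = 5, seed = 1, ...) {
  classifier <- match.arg(classifier)
  x <- as.matrix(table$values)
  stopifnot_finite(x, "feature matrix")
  y <- as_binary_labels(table$labels)
  if (min(table(y)) < folds)
    stop("need at least `folds` samples per class")
  fold_of <- stratified_folds(y, folds, seed)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
    model <- fit_classifier(classifier, xs[tr, , drop = FALSE], y[tr], ...)
    pred <- predict(model, xs[!tr, , drop = FALSE])
    truth <- y[!tr]
    tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
    fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
    per_fold[[f]] <- data.frame(fold = f, TP = tp, TN = tn, FP = fp, FN = fn,
                                t(compute_metrics(tp, tn, fp, fn)))
  }
  per_fold <- do.call(rbind, per_fold)
  mean_metrics <- colMeans(per_fold[, c("ACC", "SEN", "SPE", "PRE", "F")])
  structure(list(per_fold = per_fold, mean_metrics = mean_metrics,
                 confusion = colSums(per_fold[, c("TP", "TN", "FP", "FN")]),
                 classifier_name = classifier, folds = folds,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold CV: ACC %.2f%%, F %.2f%%\n",
              x$classifier_name, x$folds,
              x$mean_metrics["ACC"], x$mean_metrics["F"]))
  invisible(x)
}

# ---- hemisphere summary -------------------------------------------------

LEFT_CHANNELS <- c("Fp1-F7", "F7-T1", "T1-T3", "T3-T5", "Fp1-F3")
RIGHT_CHANNELS <- c("Fp2-F8", "F8-T2", "T2-T4", "T4-T6", "Fp2-F4")

#' Hemisphere-mean classification accuracy
#'
#' Averages per-channel mean accuracies over the fixed left-hemisphere
#' (Fp1-F7, F7-T1, T1-T3, T3-T5, Fp1-F3) and right-hemisphere (Fp2-F8,
#' F8-T2, T2-T4, T4-T6, Fp2-F4) channel sets.
#'
#' @param per_channel_results named list (names = channel) of `cv_result`
#'   objects, or a named numeric vector of per-channel accuracies.
#' @return named numeric vector `c(left, right)` of mean accuracies.
#' @export
hemisphere_summary <- function(per_channel_results) {
  if (is.list(per_channel_results) && !is.numeric(per_channel_results)) {
    acc <- vapply(per_channel_results,
                  function(r) unname(r$mean_metrics["ACC"]), numeric(1))
  } else acc <- per_channel_results
  chans <- names(acc)
  unknown <- setdiff(chans, c(LEFT_CHANNELS, RIGHT_CHANNELS))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  c(left = mean(acc[chans %in% LEFT_CHANNELS]),
    right = mean(acc[chans %in% RIGHT_CHANNELS]))
}
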