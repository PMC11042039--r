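#' Binary confusion matrix
#'
#' Tallies true/false positives/negatives of predicted against actual
#' labels, with the stated positive level.
#'
#' @param actual,predicted factors (or coercible) over the same two levels.
#' @param positive the level counted as positive; defaults to the second
#'   level of `actual`.
#' @return a `confusion_matrix` list with integer fields `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_matrix <- function(actual, predicted, positive = NULL) {
  actual <- factor(actual)
  predicted <- factor(predicted, levels = levels(actual))
  if (nlevels(actual) != 2L) {
    stop("confusion_matrix is defined for two classes", call. = FALSE)
  }
  if (is.null(positive)) positive <- levels(actual)[2L]
  ap <- actual == positive
  pp <- predicted == positive
  structure(list(tp = sum(ap & pp), tn = sum(!ap & !pp),
                 fp = sum(!ap & pp), fn = sum(ap & !pp)),
            class = "confusion_matrix")
}

#' Classification accuracy from a confusion matrix
#'
#' `(TP + TN) / (TP + TN + FP + FN) * 100`.
#'
#' @param cm a [confusion_matrix()].
#' @return accuracy as a percentage in \[0, 100\].
#' @examples
#' accuracy(structure(list(tp = 3, tn = 2, fp = 1, fn = 2),
#'                    class = "confusion_matrix"))  # 62.5
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  (cm$tp + cm$tn) / total * 100
}

#' Min-max normalization fitted on the training split
#'
#' Per feature column, subtracts the training minimum and divides by the
#' training range. Test values are transformed with the training
#' parameters and are NOT clipped, so they may fall outside \[0, 1\].
#' A constant training column maps to 0 everywhere.
#'
#' @param train,test numeric matrices (or [feature_matrix()] objects) with
#'   the same columns; `test` may be `NULL`.
#' @return list with normalized `train` and `test` matrices.
#' @examples
#' min_max_normalize(matrix(c(0, 5, 10), 3, 1))$train  # 0, 0.5, 1
#' @export
min_max_normalize <- function(train, test = NULL) {
  tr <- if (inherits(train, "feature_matrix")) train$x else as.matrix(train)
  te <- if (is.null(test)) NULL else
    if (inherits(test, "feature_matrix")) test$x else as.matrix(test)
  if (anyNA(tr) || (!is.null(te) && anyNA(te))) {
    stop("normalization requires complete matrices (impute first)",
         call. = FALSE)
  }
  lo <- apply(tr, 2, min)
  rng <- apply(tr, 2, max) - lo
  scale1 <- function(m) {
    out <- sweep(m, 2, lo)
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng == 0] <- 0
    out
  }
  list(train = scale1(tr), test = if (is.null(te)) NULL else scale1(te))
}

# Stratified train/test split of row indices; errors if any class fails to
# appear on both sides.
stratified_split <- function(label, train_fraction, seed) {
  set.seed(as.integer(seed))
  train <- integer(0)
  for (lv in levels(label)) {
    idx <- which(label == lv)
    n_tr <- round(train_fraction * length(idx))
    if (n_tr < 1L || n_tr >= length(idx)) {
      stop("class '", lv, "' cannot be split into train and test",
           call. = FALSE)
    }
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Fit one classifier on the training split and predict the test labels.
# All models come from established libraries; the neighbor classifier is
# Euclidean by construction.
classify <- function(train_x, train_y, test_x,
                     classifier = c("knn", "naive_bayes", "decision_tree",
                                    "neural_network"),
                     seed = 1L) {
  classifier <- match.arg(classifier)
  set.seed(as.integer(seed))
  switch(classifier,
    knn = class::knn(train_x, test_x, train_y, k = 5L),
    naive_bayes = {
      fit <- e1071::naiveBayes(train_x, train_y)
      stats::predict(fit, test_x)
    },
    decision_tree = {
      df <- data.frame(train_x); df$.y <- train_y
      fit <- rpart::rpart(.y ~ ., df, method = "class")
      stats::predict(fit, data.frame(test_x), type = "class")
    },
    neural_network = {
      df <- data.frame(train_x); df$.y <- train_y
      fit <- nnet::nnet(.y ~ ., df, size = 8L, decay = 0.01, maxit = 200L,
                        trace = FALSE)
      cls <- stats::predict(fit, data.frame(test_x), type = "class")
      factor(cls, levels = levels(train_y))
    })
}

#' Benchmark missing-data handlers by downstream classification accuracy
#'
#' For every (imputer, k, classifier) cell: handle the missing data, split
#' the resulting rows into stratified train/test sets, min-max normalize
#' with training parameters, fit the classifier, and score held-out
#' accuracy through the confusion matrix. Fuzzy imputers sweep the `k`
#' grid; the conventional baselines do not take `k`. A cell that cannot
#' run (for example listwise deletion emptying a class) is reported with
#' `NA` accuracy and its error in `status`; the run continues.
#'
#' @param fm a labelled [feature_matrix()] (two or more classes; the
#'   confusion-matrix accuracy requires two).
#' @param imputers fuzzy methods to sweep over `k_grid`.
#' @param baselines k-free handlers to include.
#' @param k_grid neighbor counts for the fuzzy methods.
#' @param classifiers classifier identifiers (see [classify] internals:
#'   Euclidean nearest neighbors, Gaussian naive Bayes, decision tree,
#'   multi-layer perceptron).
#' @param train_fraction stratified training fraction.
#' @param seed master seed; every cell derives its own seed from it, so a
#'   repeated run is identical.
#' @param dataset_id label carried into the result rows.
#' @return data.frame with one row per cell: `dataset`, `imputer`, `k`,
#'   `classifier`, `accuracy` (percent, `NA` on failure), `status`.
#' @export
run_benchmark <- function(fm,
                          imputers = c("triangular", "gaussian"),
                          baselines = c("mean", "median", "listwise", "none"),
                          k_grid = c(3L, 5L, 7L, 9L),
                          classifiers = c("knn", "naive_bayes",
                                          "decision_tree", "neural_network"),
                          train_fraction = 0.8, seed = 1L,
                          dataset_id = "dataset") {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$label)) stop("benchmark requires a labelled dataset",
                              call. = FALSE)
  plan <- rbind(
    expand.grid(imputer = imputers, k = as.integer(k_grid),
                stringsAsFactors = FALSE),
    if (length(baselines))
      data.frame(imputer = baselines, k = NA_integer_))
  rows <- list()
  cell_id <- 0L
  for (p in seq_len(nrow(plan))) {
    method <- plan$imputer[p]; k <- plan$k[p]
    handled <- tryCatch(
      apply_imputer(fm, method, k = if (is.na(k)) 3L else k),
      error = function(e) e)
    for (cl in classifiers) {
      cell_id <- cell_id + 1L
      # the seed is shared across imputers for a given classifier, so every
      # method is scored on the same train/test partition
      cell_seed <- as.integer(seed) + 7919L * match(cl, classifiers)
      res <- if (inherits(handled, "error")) handled else tryCatch({
        tr_idx <- stratified_split(handled$label, train_fraction, cell_seed)
        norm <- min_max_normalize(handled$x[tr_idx, , drop = FALSE],
                                  handled$x[-tr_idx, , drop = FALSE])
        pred <- classify(norm$train, handled$label[tr_idx], norm$test,
                         cl, seed = cell_seed)
        actual <- handled$label[-tr_idx]
        if (nlevels(actual) == 2L) {
          accuracy(confusion_matrix(actual, pred))
        } else {
          mean(pred == actual, na.rm = TRUE) * 100
        }
      }, error = function(e) e)
      failed <- inherits(res, "error")
      rows[[cell_id]] <- data.frame(
        dataset = dataset_id, imputer = method, k = k, classifier = cl,
        accuracy = if (failed) NA_real_ else res,
        status = if (failed) paste0("failed: ", conditionMessage(res)) else "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Average benchmark accuracies over datasets
#'
#' Groups results by (imputer, k, classifier), averages accuracy across
#' datasets, and returns the table ranked by mean accuracy.
#'
#' @param results a data.frame from [run_benchmark()] (rows from several
#'   datasets may be concatenated).
#' @return data.frame `imputer`, `k`, `classifier`, `mean_accuracy`,
#'   `n_datasets`, sorted by decreasing mean accuracy.
#' @export
summarize_benchmark <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("no benchmark results to summarize", call. = FALSE)
  }
  ok <- results[results$status == "ok", , drop = FALSE]
  key <- interaction(ok$imputer, ifelse(is.na(ok$k), "-", ok$k),
                     ok$classifier, drop = TRUE)
  agg <- lapply(split(ok, key), function(g) {
    data.frame(imputer = g$imputer[1L], k = g$k[1L],
               classifier = g$classifier[1L],
               mean_accuracy = mean(g$accuracy),
               n_datasets = length(unique(g$dataset)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$mean_accuracy), , drop = FALSE]
  rownames(out) <- NULL
  out
}
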