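test_that("confusion-matrix accuracy follows the closed-form definition", {
  cm <- structure(list(tp = 1, tn = 1, fp = 1, fn = 1),
                  class = "confusion_matrix")
  expect_equal(accuracy(cm), 50)
  cm <- structure(list(tp = 4, tn = 6, fp = 0, fn = 0),
                  class = "confusion_matrix")
  expect_equal(accuracy(cm), 100)
  cm <- structure(list(tp = 3, tn = 2, fp = 1, fn = 2),
                  class = "confusion_matrix")
  expect_equal(accuracy(cm), 62.5)
  expect_error(accuracy(structure(list(tp = 0, tn = 0, fp = 0, fn = 0),
                                  class = "confusion_matrix")), "empty")
})

test_that("confusion_matrix tallies the four cells against the positive level", {
  actual <- factor(c(1, 1, 1, 0, 0, 0, 1), levels = c(0, 1))
  pred   <- factor(c(1, 1, 0, 0, 1, 0, 0), levels = c(0, 1))
  cm <- confusion_matrix(actual, pred, positive = "1")
  expect_equal(cm$tp, 2); expect_equal(cm$fn, 2)
  expect_equal(cm$fp, 1); expect_equal(cm$tn, 2)
  expect_equal(accuracy(cm), 100 * 4 / 7)
})

test_that("min-max normalization fits on train and leaves test unclipped", {
  norm <- min_max_normalize(matrix(c(0, 5, 10), 3, 1))
  expect_equal(norm$train[, 1], c(0, 0.5, 1))
  # constant train column maps to zero
  norm <- min_max_normalize(matrix(7, 4, 1), matrix(c(7, 9), 2, 1))
  expect_equal(norm$train[, 1], rep(0, 4))
  expect_equal(norm$test[, 1], rep(0, 2))
  # test values outside the train range pass through unclipped
  norm <- min_max_normalize(matrix(c(0, 10), 2, 1), matrix(12, 1, 1))
  expect_equal(norm$test[1, 1], 1.2)
  # every non-constant normalized train column spans [0, 1] exactly
  set.seed(14)
  tr <- matrix(rnorm(60), 20, 3)
  norm <- min_max_normalize(tr)
  expect_equal(unname(apply(norm$train, 2, min)), rep(0, 3))
  expect_equal(unname(apply(norm$train, 2, max)), rep(1, 3))
  expect_error(min_max_normalize(matrix(c(NA, 1), 2, 1)), "complete")
})

test_that("the benchmark emits the full grid and is seed-reproducible", {
  fm <- generate_synthetic(synthetic_spec(n_rows = 120, n_features = 5,
                                          seed = 30))
  inj <- inject_mcar(fm, 0.05, seed = 30)
  res <- run_benchmark(inj$matrix, seed = 99, dataset_id = "synth")
  # 2 fuzzy imputers x 4 k x 4 classifiers, plus 4 baselines x 4 classifiers
  expect_equal(nrow(res), 48L)
  fuzzy <- res[res$imputer %in% c("triangular", "gaussian"), ]
  expect_equal(nrow(fuzzy), 32L)
  expect_true(all(!is.na(fuzzy$k)))
  expect_true(all(res$accuracy[res$status == "ok"] >= 0 &
                  res$accuracy[res$status == "ok"] <= 100))
  # the incomplete "none" cells are reported as failed, not dropped
  expect_true(all(res$status[res$imputer == "none"] != "ok"))
  res2 <- run_benchmark(inj$matrix, seed = 99, dataset_id = "synth")
  expect_identical(res, res2)
})

test_that("imputation is a no-op on complete data, so none and mean agree", {
  fm <- generate_synthetic(synthetic_spec(n_rows = 100, n_features = 4,
                                          seed = 31))
  res <- run_benchmark(fm, imputers = character(0),
                       baselines = c("none", "mean"),
                       classifiers = c("knn", "decision_tree"), seed = 5)
  none <- res[res$imputer == "none", c("classifier", "accuracy")]
  mean_ <- res[res$imputer == "mean", c("classifier", "accuracy")]
  expect_equal(none$accuracy[order(none$classifier)],
               mean_$accuracy[order(mean_$classifier)])
})

test_that("well-separated synthetic data beats the majority-class rate after imputation", {
  fm <- generate_synthetic(synthetic_spec(n_rows = 150, n_features = 5,
                                          effect_size = 2, seed = 32))
  inj <- inject_mcar(fm, 0.05, seed = 32)
  majority <- max(table(fm$label)) / length(fm$label) * 100
  res <- run_benchmark(inj$matrix, imputers = "triangular",
                       baselines = character(0), k_grid = 3,
                       classifiers = c("knn", "naive_bayes"), seed = 12)
  expect_true(all(res$status == "ok"))
  expect_true(all(res$accuracy > majority))
})

test_that("summarize averages accuracy over datasets and ranks the table", {
  fixture <- data.frame(
    dataset = c("d1", "d2", "d1", "d2", "d1", "d2"),
    imputer = c("triangular", "triangular", "mean", "mean", "gaussian",
                "gaussian"),
    k = c(3L, 3L, NA, NA, 3L, 3L),
    classifier = "knn",
    accuracy = c(80, 90, 70, 74, 85, 87),
    status = "ok", stringsAsFactors = FALSE)
  summ <- summarize_benchmark(fixture)
  expect_equal(nrow(summ), 3L)
  expect_equal(summ$mean_accuracy, c(86, 85, 72))  # ranked descending
  expect_equal(summ$imputer, c("gaussian", "triangular", "mean"))
  expect_true(all(summ$n_datasets == 2L))
  one <- summarize_benchmark(fixture[1, ])
  expect_equal(one$mean_accuracy, 80)
  expect_error(summarize_benchmark(fixture[0, ]), "no benchmark")
})

test_that("listwise deletion that empties a class fails that cell and continues", {
  x <- matrix(rnorm(40), 20, 2)
  x[1:10, 1] <- NA  # wipe every positive-class row
  fm <- feature_matrix(x, label = rep(c("pos", "neg"), each = 10))
  res <- run_benchmark(fm, imputers = character(0),
                       baselines = c("listwise", "mean"),
                       classifiers = "knn", seed = 3)
  expect_match(res$status[res$imputer == "listwise"], "failed")
  expect_true(is.na(res$accuracy[res$imputer == "listwise"]))
  expect_equal(res$status[res$imputer == "mean"], "ok")
})
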