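test_that("confusion-matrix metrics match hand-derived values", {
  cm <- list(TP = 10, TN = 10, FP = 1, FN = 0)
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 95.24)
  expect_equal(m$precision_weighted, 95.67)
  expect_equal(m$recall_weighted, 95.24)
  expect_equal(m$f1_positive, 95.24)
  expect_equal(m$per_class$recall[m$per_class$class == "healthy"], 90.91)

  perfect <- metrics_from_confusion(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$precision_weighted, 100)
  expect_equal(perfect$f1_positive, 100)

  # all predicted positive on a balanced set
  allpos <- metrics_from_confusion(confusion_matrix(
    rep(c("healthy", "parkinson"), each = 5), rep("parkinson", 10)))
  expect_equal(allpos$accuracy, 50)
  expect_equal(allpos$cm$FP, 5)
  # healthy precision undefined (no healthy predictions)
  expect_true(is.nan(allpos$per_class$precision[1]))
})

test_that("metrics agree with a brute-force recount of prediction pairs", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    truth <- sample(c("healthy", "parkinson"), n, replace = TRUE)
    pred <- sample(c("healthy", "parkinson"), n, replace = TRUE)
    m <- metrics_from_confusion(confusion_matrix(truth, pred))
    # naive recount
    acc <- round(100 * mean(truth == pred), 2)
    expect_equal(m$accuracy, acc)
    tp <- sum(truth == "parkinson" & pred == "parkinson")
    fp <- sum(truth == "healthy" & pred == "parkinson")
    fn <- sum(truth == "parkinson" & pred == "healthy")
    f1 <- if (2 * tp + fp + fn == 0) NaN else round(100 * 2 * tp / (2 * tp + fp + fn), 2)
    expect_equal(m$f1_positive, f1)
    # weighted recall equals accuracy for complete binary predictions
    if (length(unique(truth)) == 2) expect_equal(m$recall_weighted, acc)
  }
})

test_that("grid search is deterministic and validates its inputs", {
  tab <- blob_table(10)
  m1 <- train_grid_search(tab, "rf", seed = 5)
  m2 <- train_grid_search(tab, "rf", seed = 5)
  expect_identical(m1$chosen_hyperparameters, m2$chosen_hyperparameters)
  expect_identical(m1$cv_results$mean_cv_accuracy, m2$cv_results$mean_cv_accuracy)

  expect_error(train_grid_search(blob_table(2), "rf"), "at least 10")
  one_class <- blob_table(10)
  one_class$label <- "healthy"
  expect_error(train_grid_search(one_class, "rf"), "single class")
})

test_that("well-separated classes are classified perfectly by every learner", {
  tab <- blob_table(15, gap = 20, seed = 8)
  sp <- split_table(tab, 0.25, seed = 2)
  for (alg in c("rf", "dt", "svm", "xgboost", "adaboost")) {
    m <- train_grid_search(sp$train, alg, seed = 3)
    ev <- evaluate(m, sp$test)
    if (alg %in% c("rf", "dt", "svm")) {
      expect_equal(ev$accuracy, 100, label = alg)
    } else {
      # tree boosters may place the split at a cluster edge rather than
      # mid-gap, so a test point just outside the training range can miss
      expect_gte(ev$accuracy, 85)
    }
    expect_gte(max(m$cv_results$mean_cv_accuracy), 0.94)
  }
})

test_that("fold-wise scaling never leaks validation data", {
  tab <- blob_table(10, gap = 6, seed = 20)
  grid <- list(max_depth = 3)
  m <- train_grid_search(tab, "dt", grid = grid, seed = 17)
  # wildly perturb the rows of validation fold 1: results of folds 2..5,
  # whose scalers and training data exclude those rows, must be unchanged
  y <- factor(tab$label, levels = c("healthy", "parkinson"))
  folds <- spiralpd:::make_folds(y, 5L, 17L)
  tab2 <- tab
  cols <- spiralpd:::feature_columns("FP")
  tab2[folds == 1, cols] <- tab2[folds == 1, cols] * 100 + 50
  m2 <- train_grid_search(tab2, "dt", grid = grid, seed = 17)
  expect_identical(m$fold_accuracies[1, 2:5], m2$fold_accuracies[1, 2:5])
})

test_that("evaluate rejects mismatched feature sets", {
  tab <- blob_table(10)
  m <- train_grid_search(tab, "dt", seed = 1)
  expect_error(evaluate(m, subset_features(tab, "F")), "mismatch")
})

test_that("single drawings are classified or flagged unusable", {
  set <- cached("predict_set", make_labeled_set(
    10, 10, spiral_ranges("healthy", 2), spiral_ranges("parkinson", 2),
    seed = 41))
  tab <- cached("predict_tab", build_feature_table(set, feature_set = "FP"))
  model <- train_grid_search(clean_table(tab), "rf", seed = 2)

  healthy_img <- render_spiral(test_spec(seed = 99, stroke_intensity = 80))
  expect_equal(predict_image(model, healthy_img), "healthy")
  expect_equal(predict_image(model, crossing_image()), "unusable")

  pmodel <- train_grid_search(subset_features(clean_table(tab), "P"), "rf",
                              seed = 2)
  expect_equal(predict_image(pmodel, matrix(255, 60, 60)), "unusable")
})
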