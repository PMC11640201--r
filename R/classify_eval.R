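#' Default hyperparameter grids
#'
#' One named list per supported algorithm; every element can be overridden by
#' passing a custom grid to [train_grid_search()]. `max_depth = 0` means
#' unlimited depth for the random forest; `max_depth = 30` is rpart's
#' maximum and stands for "unlimited" for the decision tree.
#'
#' @return Named list of grids (each a named list of candidate values).
#' @export
default_grids <- function() {
  list(
    dt = list(max_depth = c(3, 5, 10, 30)),
    rf = list(num_trees = c(100, 300, 500), max_depth = c(0, 5, 10)),
    svm = list(kernel = c("radial", "linear"), cost = c(0.1, 1, 10)),
    xgboost = list(nrounds = c(100, 300), eta = c(0.05, 0.1), max_depth = c(3, 6)),
    adaboost = list(n_estimators = c(50, 200), learning_rate = c(0.5, 1.0))
  )
}

spiral_classes <- c("healthy", "parkinson")

# ---- learners -------------------------------------------------------------

# Each fitter returns a list(predict = function(Xnew) factor, ...).
fit_learner <- function(algorithm, params, X, y, seed) {
  y <- factor(y, levels = spiral_classes)
  df <- data.frame(X, label = y, check.names = FALSE)
  switch(
    algorithm,
    dt = {
      fit <- rpart::rpart(
        label ~ ., data = df, method = "class",
        control = rpart::rpart.control(maxdepth = params$max_depth, cp = 0.001,
                                       minsplit = 5, xval = 0)
      )
      list(predict = function(Xn) {
        p <- predict(fit, data.frame(Xn, check.names = FALSE), type = "class")
        factor(as.character(p), levels = spiral_classes)
      })
    },
    rf = {
      fit <- ranger::ranger(
        label ~ ., data = df, num.trees = params$num_trees,
        max.depth = params$max_depth, seed = seed, num.threads = 1,
        classification = TRUE
      )
      list(predict = function(Xn) {
        p <- predict(fit, data.frame(Xn, check.names = FALSE),
                     num.threads = 1)$predictions
        factor(as.character(p), levels = spiral_classes)
      })
    },
    svm = {
      fit <- e1071::svm(X, y, kernel = params$kernel, cost = params$cost,
                        scale = FALSE)
      list(predict = function(Xn) {
        factor(as.character(predict(fit, Xn)), levels = spiral_classes)
      })
    },
    xgboost = {
      yb <- as.integer(y == "parkinson")
      dm <- xgboost::xgb.DMatrix(X, label = yb, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      learning_rate = params$eta,
                      max_depth = params$max_depth,
                      nthread = 1, seed = seed),
        data = dm, nrounds = params$nrounds, verbose = 0
      )
      list(predict = function(Xn) {
        p <- predict(fit, xgboost::xgb.DMatrix(Xn, nthread = 1))
        factor(ifelse(p > 0.5, "parkinson", "healthy"), levels = spiral_classes)
      })
    },
    adaboost = fit_adaboost(X, y, params$n_estimators, params$learning_rate),
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE)
  )
}

# SAMME AdaBoost over depth-1 rpart stumps (discrete boosting, two classes).
fit_adaboost <- function(X, y, n_estimators, learning_rate) {
  n <- nrow(X)
  yy <- ifelse(y == "parkinson", 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(X, check.names = FALSE)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(
      label ~ ., data = data.frame(df, label = factor(y, levels = spiral_classes)),
      weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                                     minbucket = 1, xval = 0)
    )
    pred <- ifelse(predict(fit, df, type = "class") == "parkinson", 1, -1)
    err <- sum(w * (pred != yy))
    if (err <= 0) {
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, 10)  # perfect stump dominates
      break
    }
    if (err >= 0.5) break
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {
    # degenerate: majority vote
    maj <- names(which.max(table(y)))
    return(list(predict = function(Xn) {
      factor(rep(maj, nrow(Xn)), levels = spiral_classes)
    }))
  }
  list(predict = function(Xn) {
    dfn <- data.frame(Xn, check.names = FALSE)
    score <- rep(0, nrow(dfn))
    for (m in seq_along(stumps)) {
      pm <- ifelse(predict(stumps[[m]], dfn, type = "class") == "parkinson", 1, -1)
      score <- score + alphas[m] * pm
    }
    factor(ifelse(score >= 0, "parkinson", "healthy"), levels = spiral_classes)
  })
}

# Stratified fold assignment, reproducible under seed.
make_folds <- function(y, cv, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      ix <- which(y == cl)
      f[ix] <- sample(rep(seq_len(cv), length.out = length(ix)))
    }
    f
  })
}

# ---- scaling --------------------------------------------------------------

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# ---- training -------------------------------------------------------------

#' Train a classifier with grid search and five-fold cross-validation
#'
#' For every grid point, runs stratified `cv`-fold cross-validation in which
#' each fold's z-score scaler is fitted on that fold's training portion only
#' and then applied to its validation portion, preventing any leakage of
#' validation statistics into training. The grid point with the highest mean
#' CV accuracy wins (ties go to the first point in declared order); the final
#' model is refitted on all training rows with a scaler fitted on all
#' training rows.
#'
#' @param table A `feature_table` of training rows (both classes present,
#'   at least 10 rows).
#' @param algorithm One of `"rf"`, `"dt"`, `"svm"`, `"xgboost"`,
#'   `"adaboost"`.
#' @param grid Named list of candidate hyperparameter values; defaults to
#'   [default_grids()] for the algorithm.
#' @param seed Integer seed driving fold shuffling and stochastic learners.
#' @param cv Number of folds (default 5).
#' @return An object of class `spiral_model` with the fitted scaler,
#'   classifier, chosen hyperparameters and CV results.
#' @export
train_grid_search <- function(table, algorithm = c("rf", "dt", "svm", "xgboost", "adaboost"),
                              grid = NULL, seed = 1L, cv = 5L) {
  algorithm <- match.arg(algorithm)
  fs <- feature_set_of(table)
  cols <- feature_columns(fs)
  if (nrow(table) < 10) stop("need at least 10 training rows", call. = FALSE)
  y <- factor(table$label, levels = spiral_classes)
  if (any(is.na(y))) stop("labels must be healthy/parkinson", call. = FALSE)
  if (length(unique(y)) < 2) stop("training table has a single class", call. = FALSE)
  if (min(table(y)) < cv) {
    stop(sprintf("cannot stratify %d folds: smallest class has %d rows",
                 cv, min(table(y))), call. = FALSE)
  }
  X <- as.matrix(table[, cols, drop = FALSE])
  if (any(is.na(X))) stop("training table contains NaN features; run clean_table() first",
                          call. = FALSE)
  if (is.null(grid)) grid <- default_grids()[[algorithm]]
  grid_df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)

  folds <- make_folds(y, cv, seed)

  fold_accuracies <- matrix(NA_real_, nrow(grid_df), cv)
  for (g in seq_len(nrow(grid_df))) {
    params <- as.list(grid_df[g, , drop = FALSE])
    for (k in seq_len(cv)) {
      tr <- folds != k
      scaler <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(scaler, X[tr, , drop = FALSE])
      Xva <- apply_scaler(scaler, X[!tr, , drop = FALSE])
      fit <- fit_learner(algorithm, params, Xtr, y[tr], seed = seed + 1000L * g + k)
      fold_accuracies[g, k] <- mean(fit$predict(Xva) == y[!tr])
    }
  }
  acc <- rowMeans(fold_accuracies)
  best <- which.max(acc)  # first index on ties
  best_params <- as.list(grid_df[best, , drop = FALSE])

  scaler <- fit_scaler(X)
  final <- fit_learner(algorithm, best_params, apply_scaler(scaler, X), y,
                       seed = seed)
  structure(
    list(
      algorithm = algorithm,
      feature_set = fs,
      feature_cols = cols,
      scaler = scaler,
      fit = final,
      chosen_hyperparameters = best_params,
      cv_results = cbind(grid_df, mean_cv_accuracy = acc),
      fold_accuracies = fold_accuracies,
      folds = folds,
      cv = cv,
      seed = as.integer(seed),
      n_train = nrow(table)
    ),
    class = "spiral_model"
  )
}

#' @export
print.spiral_model <- function(x, ...) {
  cat(sprintf("spiral_model: %s on %s features (%d training rows)\n",
              toupper(x$algorithm), x$feature_set, x$n_train))
  hp <- paste(names(x$chosen_hyperparameters),
              unlist(x$chosen_hyperparameters), sep = " = ", collapse = ", ")
  cat(sprintf("  chosen hyperparameters: %s\n", hp))
  cat(sprintf("  best mean CV accuracy: %.2f%% (cv = %d)\n",
              100 * max(x$cv_results$mean_cv_accuracy), x$cv))
  invisible(x)
}

#' @export
summary.spiral_model <- function(object, ...) {
  print(object)
  cat("\nGrid search results:\n")
  print(object$cv_results, row.names = FALSE)
  invisible(object)
}

#' Predict classes for a feature table
#'
#' @param object A `spiral_model`.
#' @param newdata A `feature_table` (or data frame with the model's feature
#'   columns).
#' @param ... Unused.
#' @return Factor of predicted labels (levels healthy, parkinson).
#' @export
predict.spiral_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  if (any(is.na(X))) stop("newdata contains NaN features", call. = FALSE)
  object$fit$predict(apply_scaler(object$scaler, X))
}

# ---- evaluation -----------------------------------------------------------

#' Confusion matrix counts for binary predictions
#'
#' @param truth,pred Vectors of `healthy`/`parkinson` labels; `parkinson` is
#'   the positive class.
#' @return Object of class `confusion_matrix` with counts `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- factor(as.character(truth), levels = spiral_classes)
  pred <- factor(as.character(pred), levels = spiral_classes)
  if (any(is.na(truth)) || any(is.na(pred))) {
    stop("labels must be healthy/parkinson", call. = FALSE)
  }
  structure(
    list(
      TP = sum(truth == "parkinson" & pred == "parkinson"),
      TN = sum(truth == "healthy" & pred == "healthy"),
      FP = sum(truth == "healthy" & pred == "parkinson"),
      FN = sum(truth == "parkinson" & pred == "healthy")
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(truth = spiral_classes, predicted = spiral_classes))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes, as percentages rounded to two decimals: accuracy
#' \eqn{(TP+TN)/(TP+TN+FP+FN)}, per-class precision, recall and F1, the
#' positive-class F1 \eqn{2TP/(2TP+FP+FN)}, and support-weighted averages of
#' precision, recall and F1 (weights are the true class counts). Ratios with
#' zero denominators are `NaN`.
#'
#' @param cm A `confusion_matrix` (or list with `TP`, `TN`, `FP`, `FN`).
#' @return Named list of metrics (percentages) plus the per-class table.
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  total <- tp + tn + fp + fn
  if (is.null(total) || total <= 0) stop("empty confusion matrix", call. = FALSE)
  rat <- function(num, den) if (den == 0) NaN else num / den

  # positive class = parkinson
  prec_pos <- rat(tp, tp + fp)
  rec_pos <- rat(tp, tp + fn)
  f1_pos <- rat(2 * tp, 2 * tp + fp + fn)
  # negative class = healthy
  prec_neg <- rat(tn, tn + fn)
  rec_neg <- rat(tn, tn + fp)
  f1_neg <- rat(2 * tn, 2 * tn + fn + fp)

  sup_pos <- tp + fn
  sup_neg <- tn + fp
  wavg <- function(a, b) rat(sup_neg * a + sup_pos * b, sup_neg + sup_pos)

  pct <- function(v) if (is.nan(v)) NaN else round(100 * v, 2)
  per_class <- data.frame(
    class = spiral_classes,
    precision = c(pct(prec_neg), pct(prec_pos)),
    recall = c(pct(rec_neg), pct(rec_pos)),
    f1 = c(pct(f1_neg), pct(f1_pos)),
    support = c(sup_neg, sup_pos)
  )
  list(
    accuracy = pct(rat(tp + tn, total)),
    precision_weighted = pct(wavg(prec_neg, prec_pos)),
    recall_weighted = pct(wavg(rec_neg, rec_pos)),
    f1_positive = pct(f1_pos),
    f1_weighted = pct(wavg(f1_neg, f1_pos)),
    per_class = per_class,
    cm = cm
  )
}

#' Evaluate a trained model on a held-out feature table
#'
#' Applies the stored scaler and classifier to the test rows and summarises
#' the predictions as a confusion matrix and the metric bundle of
#' [metrics_from_confusion()].
#'
#' @param model A `spiral_model`.
#' @param table A `feature_table` with the same feature set.
#' @return Object of class `spiral_eval`.
#' @export
evaluate <- function(model, table) {
  stopifnot(inherits(model, "spiral_model"))
  if (nrow(table) == 0) stop("empty test table", call. = FALSE)
  if (!identical(feature_set_of(table), model$feature_set)) {
    stop(sprintf("feature-set mismatch: model uses %s, table is %s",
                 model$feature_set, feature_set_of(table)), call. = FALSE)
  }
  pred <- predict(model, table)
  truth <- factor(table$label, levels = spiral_classes)
  cm <- confusion_matrix(truth, pred)
  structure(
    c(metrics_from_confusion(cm),
      list(algorithm = model$algorithm, feature_set = model$feature_set,
           chosen_hyperparameters = model$chosen_hyperparameters,
           predictions = pred, n_test = nrow(table))),
    class = "spiral_eval"
  )
}

#' @export
print.spiral_eval <- function(x, ...) {
  cat(sprintf("Evaluation: %s on %s features, %d test rows\n",
              toupper(x$algorithm), x$feature_set, x$n_test))
  cat(sprintf("  accuracy %.2f%% | weighted precision %.2f%% | weighted recall %.2f%% | F1 %.2f%%\n",
              x$accuracy, x$precision_weighted, x$recall_weighted, x$f1_positive))
  cat("  confusion matrix (truth x predicted):\n")
  print(x$cm)
  invisible(x)
}

#' Classify a single drawing
#'
#' Runs the feature-extraction pipeline matching the model's feature set on
#' one image and predicts its class. Drawings whose features cannot be
#' computed (self-intersecting spiral, blank page) are reported as
#' `"unusable"` rather than guessed.
#'
#' @param model A `spiral_model`.
#' @param image Grayscale matrix in \[0, 255\], or a path to a PNG/JPEG file.
#' @param N Smoothing scale factor for the line of best fit.
#' @param draw_duration Nominal drawing time (s).
#' @return `"healthy"`, `"parkinson"` or `"unusable"`.
#' @export
predict_image <- function(model, image, N = 10, draw_duration = 10) {
  stopifnot(inherits(model, "spiral_model"))
  if (is.character(image)) image <- read_spiral_image(image)
  assert_gray_image(image)
  rec <- list()
  if (model$feature_set %in% c("F", "FP")) {
    rec <- c(rec, frequency_features_image(image, N = N, draw_duration = draw_duration))
  }
  if (model$feature_set %in% c("P", "FP")) {
    pf <- tryCatch(extract_pencil_features(image),
                   error = function(e) list(thickness = NaN, pressure = NaN))
    rec <- c(rec, pf[c("thickness", "pressure")])
  }
  vals <- unlist(rec[model$feature_cols])
  if (any(is.na(vals))) return("unusable")
  as.character(predict(model, as.data.frame(as.list(vals))))
}
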