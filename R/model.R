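#' Gradient-boosting model configuration
#'
#' The leaf-wise boosted-tree parameterization used for splicing-efficiency
#' prediction: 50 leaves, learning rate 0.1, feature fraction 0.8, bagging
#' fraction 0.8 (bagging frequency 5 is recorded for fidelity with the
#' leaf-wise reference parameterization but the backend re-subsamples each
#' round), 500 boosting rounds with early stopping after 5 stagnant
#' rounds, 5-fold averaging cross-validation on a 75/25 train/test split,
#' and 1000 bootstrap resamples for confidence intervals.
#'
#' @param num_leaves,learning_rate,feature_fraction,bagging_fraction
#'   Tree-growth and subsampling parameters.
#' @param bagging_freq Recorded, see above.
#' @param n_rounds,early_stopping Boosting schedule.
#' @param n_folds Cross-validation folds.
#' @param train_fraction Training share of the data.
#' @param n_boot Bootstrap resamples for confidence intervals.
#' @return A list of class `model_config`.
#' @export
model_config <- function(num_leaves = 50L, learning_rate = 0.1,
                         feature_fraction = 0.8, bagging_fraction = 0.8,
                         bagging_freq = 5L, n_rounds = 500L,
                         early_stopping = 5L, n_folds = 5L,
                         train_fraction = 0.75, n_boot = 1000L) {
  stopifnot(num_leaves > 0, learning_rate > 0, n_rounds > 0,
            feature_fraction > 0, feature_fraction <= 1,
            bagging_fraction > 0, bagging_fraction <= 1,
            train_fraction > 0, train_fraction < 1)
  structure(as.list(environment()), class = "model_config")
}

# one-hot encode the categorical schema features; returns the numeric
# matrix plus a map from matrix columns back to schema features
encode_features <- function(features, levels_map = NULL) {
  sch <- feature_schema()
  cat_f <- sch$name[sch$type == "categorical"]
  num_f <- sch$name[sch$type == "numeric"]
  if (is.null(levels_map))
    levels_map <- lapply(stats::setNames(cat_f, cat_f), function(f)
      sort(unique(as.character(features[[f]]))))
  blocks <- list(as.matrix(features[, num_f, drop = FALSE]))
  col_feature <- num_f
  for (f in cat_f) {
    lv <- levels_map[[f]]
    m <- outer(as.character(features[[f]]), lv, `==`) * 1
    colnames(m) <- paste0(f, "=", lv)
    blocks[[length(blocks) + 1L]] <- m
    col_feature <- c(col_feature, rep(f, length(lv)))
  }
  X <- do.call(cbind, blocks)
  list(X = X, col_feature = col_feature, levels_map = levels_map)
}

.xgb_params <- function(config) {
  list(objective = "reg:squarederror",
       tree_method = "hist", grow_policy = "lossguide",
       max_leaves = config$num_leaves, max_depth = 0L,
       eta = config$learning_rate,
       colsample_bytree = config$feature_fraction,
       subsample = config$bagging_fraction,
       nthread = 1L)
}

#' Train/test split of the variant set
#'
#' Test size is `round((1 - train_fraction) * n)`: splitting 12,667
#' variants 75/25 yields a 3,167-item test set.
#'
#' @param n Number of variants.
#' @param train_fraction Training share.
#' @param seed Seed.
#' @return A list with sorted `train` and `test` index vectors.
#' @export
split_indices <- function(n, train_fraction = 0.75, seed = 1L) {
  n_test <- round((1 - train_fraction) * n)
  with_seed(derive_seed(seed, "split"), {
    test <- sort(sample.int(n, n_test))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Train the splicing-efficiency model with 5-fold averaging CV
#'
#' Splits the variants 75/25 into training and test sets (test size
#' `round(0.25 * N)`), divides the training set into 5 folds, trains one
#' boosted-tree model per fold (4 folds to fit, the fifth as the early
#' stopping validation set), predicts the test set with each of the 5
#' models and averages the predictions. Reports the test Pearson
#' correlation with a bootstrap percentile confidence interval.
#'
#' @param features Feature data.frame following [feature_schema()] (a
#'   `variant_id` column is carried along if present).
#' @param targets Numeric splicing efficiencies in `[0, 1]`.
#' @param config A [model_config()].
#' @param seed Seed controlling the split, fold assignment and training.
#' @return An object of class `se_model`: fold boosters, encoder map,
#'   train/test indices, averaged test predictions, `r`, `r_ci`.
#' @export
train_cv <- function(features, targets, config = model_config(), seed = 1L) {
  stopifnot(nrow(features) == length(targets),
            all(targets >= 0 & targets <= 1, na.rm = TRUE))
  features <- features[, setdiff(names(features), "variant_id"), drop = FALSE]
  n <- nrow(features)
  if (n < 5L * 4L) stop("too few samples for 5-fold cross-validation")
  enc <- encode_features(features)
  split <- split_indices(n, config$train_fraction, seed)
  with_seed(derive_seed(seed, "traincv"), {
    test_idx <- split$test
    train_idx <- split$train
    fold <- sample(rep_len(seq_len(config$n_folds), length(train_idx)))

    dtest <- xgboost::xgb.DMatrix(enc$X[test_idx, , drop = FALSE],
                                  label = targets[test_idx])
    boosters <- vector("list", config$n_folds)
    test_pred <- matrix(NA_real_, length(test_idx), config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- train_idx[fold != f]
      va <- train_idx[fold == f]
      dtr <- xgboost::xgb.DMatrix(enc$X[tr, , drop = FALSE],
                                  label = targets[tr])
      dva <- xgboost::xgb.DMatrix(enc$X[va, , drop = FALSE],
                                  label = targets[va])
      bst <- xgboost::xgb.train(
        params = c(.xgb_params(config), list(seed = derive_seed(seed, f))),
        data = dtr, nrounds = config$n_rounds,
        evals = list(valid = dva),
        early_stopping_rounds = config$early_stopping, verbose = 0)
      boosters[[f]] <- bst
      test_pred[, f] <- stats::predict(bst, dtest)
    }
    pred <- rowMeans(test_pred)
    r <- stats::cor(pred, targets[test_idx])
    boot_r <- vapply(seq_len(config$n_boot), function(b) {
      j <- sample.int(length(pred), replace = TRUE)
      suppressWarnings(stats::cor(pred[j], targets[test_idx][j]))
    }, numeric(1))
    structure(list(boosters = boosters, encoder = enc, config = config,
                   train_idx = train_idx, test_idx = test_idx, fold = fold,
                   test_pred = pred, targets = targets, r = r,
                   r_ci = stats::quantile(boot_r, c(0.025, 0.975),
                                          na.rm = TRUE, names = FALSE)),
              class = "se_model")
  })
}

#' Predict splicing efficiency for new variants
#'
#' @param object A trained `se_model`.
#' @param newdata Feature data.frame following [feature_schema()].
#' @param ... Ignored.
#' @return Numeric predictions (mean over the fold models).
#' @export
predict.se_model <- function(object, newdata, ...) {
  newdata <- newdata[, setdiff(names(newdata), "variant_id"), drop = FALSE]
  enc <- encode_features(newdata, object$encoder$levels_map)
  d <- xgboost::xgb.DMatrix(enc$X)
  rowMeans(vapply(object$boosters, function(b) stats::predict(b, d),
                  numeric(nrow(newdata))))
}

#' Shapley feature importance with bootstrap confidence intervals
#'
#' Computes exact tree-Shapley attributions of every training observation
#' under each of the 5 fold models, averages them over folds, sums one-hot
#' member columns back to their categorical schema feature, ranks features
#' by mean absolute Shapley value, and attaches percentile confidence
#' intervals from resampling the observations.
#'
#' @param model A trained `se_model`.
#' @param features The feature data.frame the model was trained on.
#' @param n_boot Bootstrap resamples (default from the model config).
#' @param seed Seed for the resampling.
#' @return A list: `shap` (observations x schema features, fold-averaged,
#'   plus a `BIAS` column), `ranking` (data.frame: feature, mean_abs,
#'   ci_lo, ci_hi, ordered), `local_accuracy_error` (max |sum of
#'   attributions - prediction| over fold models).
#' @export
shapley_importance <- function(model, features, n_boot = NULL, seed = 1L) {
  if (is.null(n_boot)) n_boot <- model$config$n_boot
  features <- features[, setdiff(names(features), "variant_id"), drop = FALSE]
  enc <- encode_features(features, model$encoder$levels_map)
  idx <- model$train_idx
  X <- enc$X[idx, , drop = FALSE]
  d <- xgboost::xgb.DMatrix(X)
  sch <- feature_schema()$name
  acc <- list()
  err <- 0
  for (b in model$boosters) {
    contrib <- stats::predict(b, d, predcontrib = TRUE)
    pred <- stats::predict(b, d)
    err <- max(err, max(abs(rowSums(contrib) - pred)))
    agg <- matrix(0, nrow(contrib), length(sch) + 1L,
                  dimnames = list(NULL, c(sch, "BIAS")))
    cf <- c(model$encoder$col_feature, "BIAS")
    for (f in unique(cf)) {
      agg[, f] <- rowSums(contrib[, cf == f, drop = FALSE])
    }
    acc[[length(acc) + 1L]] <- agg
  }
  shap <- Reduce(`+`, acc) / length(acc)
  vals <- shap[, sch, drop = FALSE]
  mean_abs <- colMeans(abs(vals))
  with_seed(derive_seed(seed, "shap-boot"), {
    boot <- matrix(NA_real_, n_boot, length(sch))
    for (i in seq_len(n_boot)) {
      j <- sample.int(nrow(vals), replace = TRUE)
      boot[i, ] <- colMeans(abs(vals[j, , drop = FALSE]))
    }
    ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
    ranking <- data.frame(feature = sch, mean_abs = mean_abs,
                          ci_lo = ci[1, ], ci_hi = ci[2, ],
                          row.names = NULL)
    ranking <- ranking[order(-ranking$mean_abs), ]
    rownames(ranking) <- NULL
    list(shap = shap, ranking = ranking, local_accuracy_error = err)
  })
}
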