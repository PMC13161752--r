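#' Subject-independent classification of anesthetic agent from epochs
#'
#' Epoch-level random-forest classification (propofol = positive class 1,
#' sevoflurane = 0) under subject-level 5-fold cross-validation: all epochs
#' of a subject fall in exactly one fold, so evaluation subjects are never
#' seen in training. Out-of-fold epoch probabilities are arithmetically
#' averaged per subject and thresholded at 0.5 to classify the patient;
#' feature importance is the mean absolute TreeSHAP value over out-of-fold
#' epochs.
#'
#' The forest is trained in random-forest mode (a single boosting round of
#' `trees` parallel trees, unit learning rate, mean-of-labels leaves) and
#' then re-evaluated from its exported node table in double precision, both
#' for predictions and for exact TreeSHAP attribution.
#'
#' @name modeling
NULL

#' Random-forest configuration
#'
#' @param trees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param max_depth maximum tree depth; trees are effectively depth-unlimited
#'   at this problem size (default 15).
#' @param subsample row fraction sampled (without replacement) per tree,
#'   default 0.632 -- the expected unique fraction of a bootstrap resample.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(trees = 500, mtry = NULL, max_depth = 15,
                      subsample = 0.632) {
  structure(list(trees = trees, mtry = mtry, max_depth = max_depth,
                 subsample = subsample), class = "rf_config")
}

# Train a random forest and export its node table for double-precision
# evaluation.
fit_rf <- function(X, y, config = rf_config(), seed = 1) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("training data contains a single class")
  p <- ncol(X)
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(p))) else config$mtry
  booster <- xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror", eta = 1, base_score = 0.5,
      lambda = 0, alpha = 0, max_depth = config$max_depth,
      subsample = config$subsample, colsample_bynode = mtry / p,
      num_parallel_tree = config$trees, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1), nrounds = 1,
    verbose = 0)
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- as.data.frame(dt)
  node_of <- function(id) as.integer(sub("^[0-9]+-", "", id))
  is_leaf <- dt$Feature == "Leaf"
  feats <- colnames(X)
  structure(list(
    tree_id = as.integer(dt$Tree),
    left = ifelse(is_leaf, -1L, node_of(dt$Yes)),
    right = ifelse(is_leaf, -1L, node_of(dt$No)),
    feature = ifelse(is_leaf, -1L, match(dt$Feature, feats) - 1L),
    threshold = ifelse(is_leaf, NA_real_, dt$Split),
    value = ifelse(is_leaf, dt$Gain, 0),
    cover = dt$Cover,
    base_score = 0.5, scale = 1 / 1, # eta = 1, trees already averaged below
    n_trees = config$trees, feature_names = feats
  ), class = "rf_model")
}

# Epoch probability of the positive class, evaluated in double precision.
predict_rf <- function(model, X) {
  stopifnot(is.matrix(X), ncol(X) == length(model$feature_names))
  pr <- ensemble_predict_cpp(
    model$tree_id, model$left, model$right, model$feature,
    model$threshold, model$value, model$cover, X,
    model$base_score, model$scale)
  pmin(pmax(pr, 0), 1)
}

# Exact TreeSHAP contributions (n x p+1; last column = expected value).
shap_values_rf <- function(model, X) {
  stopifnot(is.matrix(X), ncol(X) == length(model$feature_names))
  phi <- treeshap_cpp(
    model$tree_id, model$left, model$right, model$feature,
    model$threshold, model$value, model$cover, X,
    model$base_score, model$scale)
  colnames(phi) <- c(model$feature_names, "BIAS")
  phi
}

#' Assign subjects to cross-validation folds
#'
#' Subjects are shuffled by the seed and dealt round-robin into `k` folds,
#' so fold sizes differ by at most one subject.
#'
#' @param subjects character vector of subject ids (unique or per-epoch).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return data.frame with `subject_id` and `fold` (1..k).
#' @export
make_group_folds <- function(subjects, k = 5, seed = 1) {
  ids <- unique(as.character(subjects))
  if (length(ids) < k) stop("fewer subjects than folds")
  ids <- with_seed(seed, sample(ids))
  data.frame(subject_id = ids,
             fold = rep_len(seq_len(k), length(ids)),
             stringsAsFactors = FALSE)
}

# Model matrix + 0/1 labels from a cohort feature table; drops (and counts)
# rows carrying missing-value sentinels.
table_to_xy <- function(table) {
  fn <- feature_names()
  stopifnot(all(fn %in% colnames(table)))
  X <- as.matrix(table[, fn])
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    message(sum(!keep), " epoch(s) with missing features dropped from modeling")
  }
  list(X = X[keep, , drop = FALSE],
       y = as.numeric(table$group[keep] == "propofol"),
       subject_id = as.character(table$subject_id[keep]),
       group = as.character(table$group[keep]))
}

#' Out-of-fold epoch probabilities under grouped cross-validation
#'
#' Trains one forest per fold on the other folds' epochs and emits the
#' held-out epochs' probabilities; every retained epoch receives exactly one
#' out-of-fold probability.
#'
#' @param table a `cohort_features` data.frame (17 features + `subject_id` +
#'   `group`).
#' @param folds a [make_group_folds()] assignment (default: built from
#'   `table` with `seed`).
#' @param config an [rf_config()].
#' @param seed integer seed (fold shuffle and tree growing).
#' @return A `cv_result`: `prob` (per retained epoch), `subject_id`, `group`,
#'   `fold` per epoch, fitted `models`, the `folds` table and the retained
#'   feature matrix `X`.
#' @export
crossval_predict <- function(table, folds = NULL, config = rf_config(),
                             seed = 1) {
  d <- table_to_xy(table)
  if (is.null(folds)) folds <- make_group_folds(d$subject_id, 5, seed)
  fold_of <- folds$fold[match(d$subject_id, folds$subject_id)]
  if (anyNA(fold_of)) stop("epochs from subjects absent in fold assignment")
  k <- max(folds$fold)
  prob <- rep(NA_real_, length(d$y))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    te <- !tr
    if (length(unique(d$y[tr])) < 2) {
      stop("training set for fold ", f, " contains a single class")
    }
    # leakage guard: no subject may straddle the split
    stopifnot(length(intersect(d$subject_id[tr], d$subject_id[te])) == 0)
    models[[f]] <- fit_rf(d$X[tr, , drop = FALSE], d$y[tr], config,
                          seed = child_seed(seed, f))
    prob[te] <- predict_rf(models[[f]], d$X[te, , drop = FALSE])
  }
  structure(list(prob = prob, subject_id = d$subject_id, group = d$group,
                 fold = fold_of, models = models, folds = folds, X = d$X),
            class = "cv_result")
}

#' Aggregate epoch probabilities to subject-level predictions
#'
#' Arithmetic mean of each subject's out-of-fold epoch probabilities,
#' thresholded at 0.5 (a tie counts as propofol). Also returns subject-level
#' accuracy and the 2x2 confusion matrix (rows = truth, columns =
#' prediction).
#'
#' @param cv a `cv_result` (or a list with `prob`, `subject_id`, `group`).
#' @return A `subject_predictions`: data.frame `subjects` (subject_id,
#'   mean_prob, predicted, truth), `accuracy`, `confusion`.
#' @export
aggregate_subjects <- function(cv) {
  stopifnot(!anyNA(cv$prob))
  mp <- tapply(cv$prob, cv$subject_id, mean)
  truth <- tapply(cv$group, cv$subject_id, `[`, 1)
  ids <- names(mp)
  predicted <- ifelse(mp >= 0.5, "propofol", "sevoflurane")
  lv <- c("propofol", "sevoflurane")
  confusion <- table(factor(unname(truth), lv), factor(unname(predicted), lv),
                     dnn = c("truth", "predicted"))
  structure(list(
    subjects = data.frame(subject_id = ids, mean_prob = unname(mp),
                          predicted = unname(predicted),
                          truth = unname(truth), stringsAsFactors = FALSE),
    accuracy = mean(predicted == truth),
    confusion = unclass(confusion)
  ), class = "subject_predictions")
}

#' @export
print.subject_predictions <- function(x, ...) {
  cat(sprintf("Subject-level accuracy: %.2f%% (%d/%d subjects)\n",
              100 * x$accuracy, sum(diag(x$confusion)), nrow(x$subjects)))
  print(x$confusion)
  invisible(x)
}

#' Mean-absolute-SHAP feature importance ranking
#'
#' Computes exact TreeSHAP values for every out-of-fold epoch with the model
#' of its own fold, pools them, and ranks features by mean absolute SHAP
#' (ties broken by feature-table order). Positive SHAP pushes the prediction
#' toward propofol.
#'
#' @param cv a `cv_result` from [crossval_predict()].
#' @return data.frame `feature`, `mean_abs_shap`, `rank` (1..17, importance
#'   descending); attribute `shap` holds the pooled n x 18 contribution
#'   matrix (last column the per-fold expected value) in epoch order.
#' @export
shap_importance <- function(cv) {
  p <- length(feature_names())
  phi <- matrix(NA_real_, length(cv$prob), p + 1)
  for (f in seq_along(cv$models)) {
    te <- cv$fold == f
    phi[te, ] <- shap_values_rf(cv$models[[f]], cv$X[te, , drop = FALSE])
  }
  colnames(phi) <- c(feature_names(), "BIAS")
  imp <- colMeans(abs(phi[, seq_len(p), drop = FALSE]))
  ord <- order(-imp, seq_len(p))
  out <- data.frame(feature = feature_names()[ord],
                    mean_abs_shap = unname(imp[ord]),
                    rank = seq_len(p), stringsAsFactors = FALSE)
  attr(out, "shap") <- phi
  out
}

#' Run the full subject-independent classification analysis
#'
#' Convenience wrapper: grouped folds, cross-validated probabilities,
#' subject aggregation and SHAP ranking in one call.
#'
#' @inheritParams crossval_predict
#' @param k number of folds (default 5).
#' @return List with `cv`, `subjects` ([aggregate_subjects()] result) and
#'   `importance` ([shap_importance()] result).
#' @export
classify_cohort <- function(table, k = 5, config = rf_config(), seed = 1) {
  d <- table_to_xy(table)
  folds <- make_group_folds(d$subject_id, k, seed)
  cv <- crossval_predict(table, folds, config, seed)
  list(cv = cv, subjects = aggregate_subjects(cv),
       importance = shap_importance(cv))
}
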