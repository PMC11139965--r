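#' Model configuration for severity regression
#'
#' @param k_features number of features kept by univariate selection
#'   (default 15).
#' @param test_fraction held-out fraction (default 0.20, i.e. an 80/20
#'   split).
#' @param cv_folds cross-validation folds for depth tuning (default 5).
#' @param depth_grid candidate `max_depth` values; the printed depths of the
#'   reference analysis (8--9) sit inside the default grid.
#' @param n_trees trees per forest (default 500; the source names no count).
#' @param min_node minimum observations per leaf (default 1, the reference
#'   tooling convention).
#' @param seed integer seed controlling the split, selection ties and forest
#'   bootstraps.
#' @param targets outcome columns to model.
#' @param grouped_split keep both limbs of a subject on the same side of the
#'   train/test split (default `TRUE`); `FALSE` pools limbs as independent
#'   rows.
#' @return object of class `model_config`.
#' @export
model_config <- function(k_features = 15, test_fraction = 0.20, cv_folds = 5,
                         depth_grid = c(3, 5, 7, 9, 12), n_trees = 500,
                         min_node = 1, seed = 1L,
                         targets = c("womac_total", "pain", "stiffness",
                                     "physical_function", "vas"),
                         grouped_split = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_field("test_fraction", "must lie strictly between 0 and 1")
  if (cv_folds < 2) stop_field("cv_folds", "must be >= 2")
  if (k_features < 1) stop_field("k_features", "must be >= 1")
  if (any(depth_grid < 1)) stop_field("depth_grid", "depths must be >= 1")
  structure(list(k_features = as.integer(k_features),
                 test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 depth_grid = as.integer(sort(unique(depth_grid))),
                 n_trees = as.integer(n_trees), min_node = as.integer(min_node),
                 seed = as.integer(seed), targets = targets,
                 grouped_split = isTRUE(grouped_split)),
            class = "model_config")
}

#' Univariate F-statistic feature selection
#'
#' Ranks features by the regression F statistic
#' `F = (n - 2) r^2 / (1 - r^2)` (monotone in the squared Pearson
#' correlation with the target) and keeps the `k` highest-scoring ones.
#' Ties break deterministically by column order; constant features score 0.
#'
#' @param x data.frame or matrix of candidate features.
#' @param y numeric target.
#' @param k number of features to keep.
#' @return list `selected` (names, ranked), `scores` (named F statistics for
#'   all features).
#' @export
select_k_best <- function(x, y, k) {
  x <- as.data.frame(x, check.names = FALSE)
  if (k > ncol(x)) stop_field("k", "exceeds the number of available features")
  if (sd(y) == 0) stop("constant target: univariate F undefined", call. = FALSE)
  n <- length(y)
  scores <- vapply(x, function(col) {
    if (sd(col) == 0) return(0)
    r2 <- cor(col, y)^2
    if (r2 >= 1) return(Inf)
    (n - 2) * r2 / (1 - r2)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  list(selected = names(x)[ord[seq_len(k)]], scores = scores)
}

rf_fit_raw <- function(x, y, n_trees, max_depth, min_node, mtry = NULL) {
  x <- as.matrix(x)
  # all features considered at every split (the convention of the reference
  # tree-ensemble tooling for regression); bagging alone decorrelates trees
  mtry <- mtry %||% ncol(x)
  trees <- .rf_fit_cpp(x, as.numeric(y), as.integer(n_trees), as.integer(mtry),
                       as.integer(max_depth), as.integer(min_node))
  structure(list(trees = trees, features = colnames(x),
                 max_depth = max_depth, n_trees = n_trees),
            class = "emgoa_rf")
}

#' Predict from a fitted random forest
#'
#' @param object an `emgoa_rf` model.
#' @param newdata data.frame or matrix with the model's feature columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.emgoa_rf <- function(object, newdata, ...) {
  x <- as.data.frame(newdata, check.names = FALSE)
  .rf_predict_cpp(object$trees, as.matrix(x[, object$features, drop = FALSE]))
}

cv_folds_assign <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

#' Fit a random-forest regressor with cross-validated depth tuning
#'
#' For each depth in the grid, a k-fold cross-validated R-squared is computed
#' on the training data; the depth maximizing mean CV R-squared is chosen
#' (ties to the smaller depth) and the final forest is refit on all training
#' rows. Deterministic given `config$seed`.
#'
#' @param x training features (data.frame/matrix).
#' @param y training target.
#' @param config a [model_config()].
#' @return an `emgoa_rf` with `cv_curve` (depth, mean CV R-squared, per-fold
#'   values) and `chosen_depth` attached.
#' @export
fit_rf <- function(x, y, config = model_config()) {
  x <- as.data.frame(x, check.names = FALSE)
  n <- nrow(x)
  if (n < config$cv_folds) stop("fewer training rows than CV folds", call. = FALSE)
  if (any(!is.finite(as.matrix(x))) || any(!is.finite(y)))
    stop("non-finite values in training data", call. = FALSE)
  set.seed(config$seed)
  fold <- cv_folds_assign(n, config$cv_folds)
  cv <- lapply(config$depth_grid, function(d) {
    r2 <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      m <- rf_fit_raw(x[tr, , drop = FALSE], y[tr], config$n_trees, d, config$min_node)
      pr <- predict(m, x[!tr, , drop = FALSE])
      yy <- y[!tr]
      1 - sum((yy - pr)^2) / sum((yy - mean(yy))^2)
    }, numeric(1))
    list(depth = d, mean_r2 = mean(r2), fold_r2 = r2)
  })
  means <- vapply(cv, `[[`, numeric(1), "mean_r2")
  chosen <- config$depth_grid[which.max(means)]  # which.max: first max, grid sorted
  model <- rf_fit_raw(x, y, config$n_trees, chosen, config$min_node)
  model$cv_curve <- data.frame(depth = config$depth_grid, mean_cv_r2 = means)
  model$cv_fold_r2 <- do.call(rbind, lapply(cv, `[[`, "fold_r2"))
  model$chosen_depth <- chosen
  model$cv_r2 <- means[match(chosen, config$depth_grid)]
  model
}

#' Regression metrics on a held-out set
#'
#' @param model an `emgoa_rf` (or `predictions` supplied directly).
#' @param x test features.
#' @param y test target (nonzero variance).
#' @param predictions optional precomputed predictions, bypassing `model`.
#' @return list `r2` (= 1 - SSE/SST), `rmse`, `pearson_r`.
#' @export
evaluate_regression <- function(model = NULL, x = NULL, y, predictions = NULL) {
  if (is.null(predictions)) predictions <- predict(model, x)
  if (length(y) == 0) stop("empty test set", call. = FALSE)
  if (var(y) == 0) stop("zero-variance test target: R^2 undefined", call. = FALSE)
  sse <- sum((y - predictions)^2)
  sst <- sum((y - mean(y))^2)
  list(r2 = 1 - sse / sst, rmse = sqrt(mean((y - predictions)^2)),
       pearson_r = if (sd(predictions) == 0) 0 else cor(y, predictions))
}

# stratified (by severity tercile of the target) train/test split, optionally
# keeping all rows of a subject together
split_train_test <- function(tbl, target, config) {
  n <- nrow(tbl)
  units <- if (config$grouped_split) tbl$subject_id else seq_len(n)
  uid <- unique(units)
  uval <- vapply(uid, function(u) mean(tbl[[target]][units == u]), numeric(1))
  strata <- cut(rank(uval, ties.method = "first"), breaks = 3, labels = FALSE)
  test_units <- character(0)
  for (s in unique(strata)) {
    ids <- uid[strata == s]
    n_test <- max(1L, round(config$test_fraction * length(ids)))
    test_units <- c(test_units, sample(as.character(ids), n_test))
  }
  test <- as.character(units) %in% test_units
  list(train = which(!test), test = which(test))
}

#' Fit and evaluate all severity targets
#'
#' For each target: an 80/20 train/test split (stratified by target tercile,
#' subjects kept intact by default), univariate selection of the top
#' `k_features` on the training rows only, depth-tuned random-forest fit, and
#' held-out evaluation. Selection and tuning never see the test rows.
#'
#' @param tbl feature table from [build_feature_table()].
#' @param config a [model_config()].
#' @return object of class `regression_report`: per-target list with
#'   `selected_features`, `chosen_depth`, `cv_curve`, `cv_r2`, `test` metrics,
#'   `model`, and the split indices.
#' @export
run_all_targets <- function(tbl, config = model_config()) {
  missing <- setdiff(config$targets, names(tbl))
  if (length(missing) > 0)
    stop(sprintf("missing target column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  preds <- predictor_columns(tbl)
  out <- list()
  for (tg in config$targets) {
    set.seed(config$seed + match(tg, config$targets))
    sp <- split_train_test(tbl, tg, config)
    xtr <- tbl[sp$train, preds, drop = FALSE]
    ytr <- tbl[[tg]][sp$train]
    sel <- select_k_best(xtr, ytr, min(config$k_features, length(preds)))
    model <- fit_rf(xtr[, sel$selected, drop = FALSE], ytr, config)
    xte <- tbl[sp$test, sel$selected, drop = FALSE]
    yte <- tbl[[tg]][sp$test]
    test <- evaluate_regression(model, xte, yte)
    out[[tg]] <- list(target = tg, selected_features = sel$selected,
                      scores = sel$scores, chosen_depth = model$chosen_depth,
                      cv_curve = model$cv_curve, cv_r2 = model$cv_r2,
                      test = test, model = model, split = sp,
                      actual = yte, predicted = predict(model, xte))
  }
  structure(out, class = "regression_report", config = config)
}
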