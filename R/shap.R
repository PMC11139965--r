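#' Interventional coalition value of a feature subset
#'
#' `v(S)` is the mean model output over the background rows with the features
#' in `S` overridden by the explained instance's values (interventional
#' expectation). `v(all features)` is exactly the model's prediction for the
#' instance; `v(empty set)` is the background mean prediction (the base
#' value).
#'
#' @param model an `emgoa_rf`, or any function mapping a feature data.frame
#'   to numeric predictions.
#' @param x single-row data.frame (or named vector) -- the instance.
#' @param subset character vector of feature names in `S` (may be empty).
#' @param background data.frame of background rows (nonempty).
#' @return scalar coalition value.
#' @export
value_function <- function(model, x, subset, background) {
  if (nrow(background) == 0) stop("empty background set", call. = FALSE)
  z <- background
  x <- as.data.frame(as.list(x), check.names = FALSE)
  for (f in subset) z[[f]] <- x[[f]][1]
  mean(predict_any(model, z))
}

predict_any <- function(model, newdata) {
  if (is.function(model)) model(newdata) else predict(model, newdata)
}

#' Exact Shapley attribution by subset enumeration
#'
#' Computes, for every feature i, the factorially weighted sum over all
#' subsets S of the remaining features of `v(S + i) - v(S)`, with `v` the
#' interventional value of [value_function()]. Exact but exponential:
#' limited to `max_features` (default 15, about 32k coalitions -- the size
#' the univariate selection step hands over).
#'
#' @param model an `emgoa_rf` or prediction function.
#' @param x single-row data.frame, the instance to explain.
#' @param background data.frame of background rows.
#' @param features feature names to attribute over (default: columns of
#'   `background`).
#' @param max_features enumeration bound.
#' @return object of class `shap_attribution`: `phi` (named vector),
#'   `base_value`, `prediction`; `base_value + sum(phi)` equals the
#'   prediction (local accuracy).
#' @export
shapley_exact <- function(model, x, background, features = colnames(background),
                          max_features = 15) {
  p <- length(features)
  if (p > max_features)
    stop(sprintf(paste0("%d features exceed the enumeration bound (%d); ",
                        "use tree_shap() for tree ensembles"), p, max_features),
         call. = FALSE)
  if (nrow(background) == 0) stop("empty background set", call. = FALSE)
  x <- as.data.frame(as.list(x), check.names = FALSE)
  B <- nrow(background)
  n_masks <- bitwShiftL(1L, p)
  # batch: one prediction call over all (mask, background row) hybrids
  big <- background[rep(seq_len(B), n_masks), , drop = FALSE]
  for (j in seq_len(p)) {
    masks_with_j <- which(bitwAnd(seq_len(n_masks) - 1L, bitwShiftL(1L, j - 1L)) != 0L)
    rows <- as.vector(outer(seq_len(B), (masks_with_j - 1L) * B, `+`))
    big[rows, features[j]] <- x[[features[j]]][1]
  }
  pr <- predict_any(model, big)
  v <- vapply(seq_len(n_masks), function(m) mean(pr[((m - 1) * B + 1):(m * B)]),
              numeric(1))
  fact <- factorial(0:p)
  phi <- stats::setNames(numeric(p), features)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (m in 0:(n_masks - 1L)) {
      if (bitwAnd(m, bit) != 0L) next
      s <- sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0L)
      w <- fact[s + 1] * fact[p - s] / fact[p + 1]  # |S|! (p-|S|-1)! / p!
      phi[j] <- phi[j] + w * (v[m + bit + 1L] - v[m + 1L])
    }
  }
  structure(list(phi = phi, base_value = v[1],
                 prediction = v[n_masks]),
            class = "shap_attribution")
}

#' Interventional TreeSHAP for the package's random forests
#'
#' Exact interventional Shapley values for a fitted tree ensemble, computed
#' per tree in closed form from its leaves (no sampling, no subset
#' enumeration) and averaged over the background rows. Agrees with
#' [shapley_exact()] to numerical precision and satisfies local accuracy:
#' `base_value + rowSums(phi)` equals the model prediction for every
#' instance.
#'
#' @param model an `emgoa_rf`.
#' @param x data.frame of instances to explain.
#' @param background data.frame of background rows (typically the training
#'   split or a seeded subsample of it).
#' @return list `phi` (instances x features matrix), `base_value` (scalar),
#'   `prediction` (vector).
#' @export
tree_shap <- function(model, x, background) {
  if (!inherits(model, "emgoa_rf"))
    stop("tree_shap requires an emgoa_rf tree ensemble", call. = FALSE)
  if (nrow(background) == 0) stop("empty background set", call. = FALSE)
  x <- as.data.frame(x, check.names = FALSE)
  xm <- as.matrix(x[, model$features, drop = FALSE])
  bm <- as.matrix(as.data.frame(background,
                                check.names = FALSE)[, model$features, drop = FALSE])
  res <- .tree_shap_cpp(model$trees, xm, bm)
  phi <- res$phi
  dimnames(phi) <- list(rownames(x), model$features)
  list(phi = phi, base_value = res$base_value,
       prediction = as.numeric(.rf_predict_cpp(model$trees, xm)))
}

#' Global feature importance from Shapley attributions
#'
#' Mean absolute Shapley value per feature over a dataset, ranked descending.
#'
#' @param phi attribution matrix (instances x features), e.g.
#'   `tree_shap(...)$phi`.
#' @param top_n rows to keep in the emitted table (default 10).
#' @return list `importance` (named, all features, descending), `top`
#'   (data.frame feature/mean_abs_shap/rank of the top `top_n`).
#' @export
global_importance <- function(phi, top_n = 10) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1,
                                       dimnames = list(NULL, names(phi)))
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  top <- utils::head(data.frame(feature = names(imp), mean_abs_shap = unname(imp),
                                rank = seq_along(imp)), top_n)
  list(importance = imp, top = top)
}

#' Direction-of-effect summary of Shapley attributions
#'
#' For each feature, the Spearman correlation between its values and its
#' Shapley values over the dataset -- a machine-checkable stand-in for the
#' beeswarm summary plot (positive means higher feature values push the
#' prediction up). Constant features or attributions get direction 0 with
#' `degenerate = TRUE`.
#'
#' @param phi attribution matrix (instances x features).
#' @param x feature data.frame aligned with `phi` rows.
#' @return data.frame: feature, mean_abs_shap, direction, degenerate, ordered
#'   by importance.
#' @export
shap_summary_table <- function(phi, x) {
  x <- as.data.frame(x, check.names = FALSE)
  feats <- colnames(phi)
  dir <- vapply(feats, function(f) {
    if (sd(x[[f]]) == 0 || sd(phi[, f]) == 0) return(NA_real_)
    cor(x[[f]], phi[, f], method = "spearman")
  }, numeric(1))
  out <- data.frame(feature = feats,
                    mean_abs_shap = colMeans(abs(phi)),
                    direction = ifelse(is.na(dir), 0, dir),
                    degenerate = is.na(dir), row.names = NULL)
  out[order(-out$mean_abs_shap), ]
}
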