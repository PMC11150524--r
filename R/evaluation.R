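#' Coefficient of determination
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2).
#'
#' @param y observed values (>= 2, non-constant).
#' @param yhat predictions of the same length.
#' @export
r2_score <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_ff("y and yhat lengths differ")
  if (length(y) < 2L) stop_ff("r2_score needs at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop_ff("r2_score undefined for zero-variance y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root-mean-square error
#'
#' sqrt(mean((y - yhat)^2)); for velocity surrogates this is reported on the
#' raw m/s scale, i.e. after inverse min-max transformation of predictions.
#'
#' @param y observed values.
#' @param yhat predictions of the same length.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L) stop_ff("rmse of empty vectors")
  if (length(y) != length(yhat)) stop_ff("y and yhat lengths differ")
  sqrt(mean((y - yhat)^2))
}

#' Held-out metric report
#'
#' @param y test targets (raw scale).
#' @param yhat test predictions (raw scale).
#' @param model model tag.
#' @return object of class `metric_report` with `r2`, `rmse`, `n_test`,
#'   `model`.
#' @export
metric_report <- function(y, yhat, model = "") {
  structure(list(model = model, r2 = r2_score(y, yhat), rmse = rmse(y, yhat),
                 n_test = length(y)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s: R2 = %.5f, RMSE = %.5g (n_test = %d)\n",
              if (nzchar(x$model)) x$model else "model", x$r2, x$rmse, x$n_test))
  invisible(x)
}

## Uniform prediction interface for curves/surfaces.
predict_any <- function(model, X) {
  if (is.function(model)) return(model(X))
  if (inherits(model, "boost_ensemble")) return(predict_ensemble(model, X))
  if (inherits(model, c("cart_model", "knn_model", "mlp_model")))
    return(predict_base(model, X))
  stop_ff("cannot predict from an object of class '%s'", class(model)[1L])
}

#' Model specification closure for curves
#'
#' Packages an AdaBoost configuration into `fit`/`predict` closures as
#' consumed by [learning_curve()].
#'
#' @param family base-model family.
#' @param hyperparams base hyperparameter list.
#' @param n_estimators boosting rounds.
#' @param seed integer RNG seed.
#' @export
model_spec <- function(family = "tree", hyperparams = list(),
                       n_estimators = 50L, seed = 1L) {
  list(fit = function(X, y)
         fit_adaboost(X, y, base_family = family, base_hyperparams = hyperparams,
                      n_estimators = n_estimators, seed = seed),
       predict = function(model, X) predict_ensemble(model, X))
}

#' Learning curve
#'
#' For each training-set size, fits the model on the first `size` rows of a
#' seeded permutation of each cross-validation training fold and records the
#' mean R^2 on those rows (train score) and on the held-out fold (CV score).
#'
#' @param spec a [model_spec()] (list with `fit` and `predict` closures).
#' @param X feature frame.
#' @param y targets.
#' @param train_sizes increasing training sizes, each >= `cv_folds` and at
#'   most the per-fold training rows.
#' @param cv_folds number of folds.
#' @param seed integer RNG seed.
#' @return data.frame with columns `size`, `train_score`, `cv_score`.
#' @export
learning_curve <- function(spec, X, y, train_sizes, cv_folds = 3L, seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  train_sizes <- as.integer(train_sizes)
  if (is.unsorted(train_sizes, strictly = TRUE)) stop_ff("train_sizes must be increasing")
  if (any(train_sizes < cv_folds)) stop_ff("each training size must be >= cv_folds")
  max_avail <- n - ceiling(n / cv_folds)
  if (any(train_sizes > max_avail))
    stop_ff("training size %d exceeds the %d rows available per fold",
            max(train_sizes), max_avail)
  fold_id <- with_seed(child_seed(seed, 7L), sample(rep_len(seq_len(cv_folds), n)))
  tr_sc <- matrix(NA_real_, length(train_sizes), cv_folds)
  cv_sc <- matrix(NA_real_, length(train_sizes), cv_folds)
  for (fd in seq_len(cv_folds)) {
    tr_rows <- which(fold_id != fd)
    te_rows <- which(fold_id == fd)
    ord <- with_seed(child_seed(seed, 100L + fd), sample(tr_rows))
    for (si in seq_along(train_sizes)) {
      rows <- ord[seq_len(train_sizes[si])]
      model <- spec$fit(X[rows, , drop = FALSE], y[rows])
      tr_sc[si, fd] <- r2_score(y[rows], spec$predict(model, X[rows, , drop = FALSE]))
      cv_sc[si, fd] <- r2_score(y[te_rows], spec$predict(model, X[te_rows, , drop = FALSE]))
    }
  }
  data.frame(size = train_sizes,
             train_score = rowMeans(tr_sc),
             cv_score = rowMeans(cv_sc))
}

#' Partial-dependence curve
#'
#' For each grid value g of the chosen feature, the average model prediction
#' over the dataset with that feature replaced by g (all other features kept
#' at their observed values).
#'
#' @param model a fitted model (ensemble, base model, or prediction
#'   function).
#' @param data feature frame of observed rows.
#' @param feature feature name to vary.
#' @param grid_size number of evenly spaced grid values over the feature's
#'   observed range.
#' @return data.frame of class `pd_curve` with columns `value` (grid) and
#'   `average_prediction`.
#' @export
partial_dependence <- function(model, data, feature, grid_size = 50L) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop_ff("partial_dependence on empty data")
  if (!feature %in% names(data)) stop_ff("feature '%s' not in data", feature)
  grid <- seq(min(data[[feature]]), max(data[[feature]]), length.out = grid_size)
  ## one batched prediction over the grid x background rows
  big <- data[rep(seq_len(nrow(data)), times = grid_size), , drop = FALSE]
  big[[feature]] <- rep(grid, each = nrow(data))
  avg <- colMeans(matrix(predict_any(model, big), nrow(data), grid_size))
  out <- data.frame(value = grid, average_prediction = avg)
  attr(out, "feature") <- feature
  class(out) <- c("pd_curve", "data.frame")
  out
}

#' Prediction surface on a tensor grid
#'
#' Evaluates the surrogate on an `nx` x `ny` tensor grid spanning (a subset
#' of) the training domain; refuses to extrapolate beyond it. Negative
#' velocity predictions are clipped to the physical floor of zero by
#' default.
#'
#' @param model fitted model or prediction function taking an (x, y) frame.
#' @param x_range,y_range numeric length-2 evaluation ranges.
#' @param domain list with `x` and `y` length-2 training ranges.
#' @param nx,ny grid resolution.
#' @param clip_negative clip predictions below zero.
#' @return data.frame with columns `x`, `y`, `U_hat`.
#' @export
prediction_surface <- function(model, x_range, y_range, domain,
                               nx = 85L, ny = 41L, clip_negative = TRUE) {
  if (x_range[1] < domain$x[1] || x_range[2] > domain$x[2] ||
      y_range[1] < domain$y[1] || y_range[2] > domain$y[2])
    stop_ff("prediction surface grid extends outside the training domain")
  gx <- seq(x_range[1], x_range[2], length.out = nx)
  gy <- seq(y_range[1], y_range[2], length.out = ny)
  d <- data.frame(x = rep(gx, times = ny), y = rep(gy, each = nx))
  U <- predict_any(model, d)
  if (clip_negative) U <- pmax(U, 0)
  data.frame(x = d$x, y = d$y, U_hat = U)
}
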