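## Floor for the per-round average loss used when a base model fits the
## (weighted) training data essentially perfectly; caps its confidence
## weight at ln(1/BETA_FLOOR).
BETA_FLOOR <- 1e-10

fit_base <- function(family, X, y, hp, weights, seed) {
  switch(family,
    tree = fit_tree(X, y,
                    max_depth = hp$max_depth %||% 8L,
                    min_samples_leaf = hp$min_samples_leaf %||% 1L,
                    weights = weights),
    knn = {
      idx <- sample.int(nrow(X), replace = TRUE, prob = weights)
      m <- list(train_X = as.matrix(X[idx, , drop = FALSE]),
                train_y = y[idx], k = hp$k %||% 2L)
      class(m) <- "knn_model"
      m
    },
    mlp = {
      idx <- sample.int(nrow(X), replace = TRUE, prob = weights)
      fit_mlp(X[idx, , drop = FALSE], y[idx],
              hidden = hp$hidden %||% c(66L, 29L),
              activation = hp$activation %||% "relu",
              learning_rate = hp$learning_rate %||% 2e-3,
              epochs = hp$epochs %||% 60L,
              batch_size = hp$batch_size %||% 512L,
              seed = seed)
    },
    stop_ff("unknown base family '%s'", family))
}

predict_base <- function(model, X) {
  if (inherits(model, "cart_model")) return(predict_tree(model, X))
  if (inherits(model, "knn_model"))
    return(knn_predict(model$train_X, model$train_y, as.matrix(X), model$k))
  if (inherits(model, "mlp_model")) return(mlp_forward(model, X))
  stop_ff("unknown base model class")
}

#' Fit an AdaBoost.R2 regression ensemble
#'
#' Sequentially fits base regressors on reweighted training data. Each round
#' t fits a base model (trees take the sample weights natively; KNN and MLP
#' bases are fitted on a weighted bootstrap resample), computes the linear
#' per-row loss l_i = |yhat_i - y_i| / max_j |yhat_j - y_j| on the full
#' training set and the weighted average loss Lbar_t = sum_i w_i l_i. A
#' round with Lbar >= 1/2 is discarded and boosting stops (an error if it is
#' the first round); otherwise the confidence beta_t = Lbar_t/(1 - Lbar_t)
#' is stored, sample weights are updated as w_i <- w_i beta_t^(1 - l_i) and
#' renormalized. A round with Lbar below 1e-12 (an essentially perfect fit)
#' is kept with a capped confidence weight and stops the sequence. Model
#' weights are w_t = ln(1/beta_t) > 0.
#'
#' @param X data.frame/matrix of features.
#' @param y numeric targets.
#' @param base_family `"tree"`, `"knn"` or `"mlp"`.
#' @param base_hyperparams named list of base-model hyperparameters
#'   (`max_depth`, `min_samples_leaf`; `k`; `hidden`, `epochs`,
#'   `learning_rate`, `batch_size`, `activation`).
#' @param n_estimators maximum number of boosting rounds (>= 1).
#' @param seed integer RNG seed (resampling and MLP initialization).
#' @param aggregation default prediction combiner, `"weighted_average"` or
#'   `"weighted_median"`.
#' @param keep_weight_history store the sample-weight vector after every
#'   round (diagnostic; O(T n) memory).
#' @return object of class `boost_ensemble`.
#' @export
fit_adaboost <- function(X, y, base_family = c("tree", "knn", "mlp"),
                         base_hyperparams = list(), n_estimators = 50L,
                         seed = 1L,
                         aggregation = c("weighted_average", "weighted_median"),
                         keep_weight_history = FALSE) {
  base_family <- match.arg(base_family)
  aggregation <- match.arg(aggregation)
  X <- as.data.frame(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop_ff("need at least 2 training rows")
  n_estimators <- as.integer(n_estimators)
  if (n_estimators < 1L) stop_ff("n_estimators must be >= 1")

  with_seed(child_seed(seed, 0L), {
    w <- rep(1 / n, n)
    models <- list(); betas <- numeric(0); avg_losses <- numeric(0)
    w_history <- if (keep_weight_history) list() else NULL
    for (t in seq_len(n_estimators)) {
      model <- fit_base(base_family, X, y, base_hyperparams, w,
                        seed = child_seed(seed, t))
      pred <- predict_base(model, X)
      err <- abs(pred - y)
      emax <- max(err)
      if (emax < .Machine$double.eps) {        # perfect fit on training data
        models[[length(models) + 1L]] <- model
        betas <- c(betas, BETA_FLOOR); avg_losses <- c(avg_losses, 0)
        break
      }
      l <- err / emax
      Lbar <- sum(w * l)
      if (Lbar >= 0.5) {
        if (t == 1L)
          stop_ff("base learner no better than random (average loss %.3f >= 0.5)", Lbar)
        break                                   # discard this round, stop
      }
      if (Lbar < 1e-12) {
        models[[length(models) + 1L]] <- model
        betas <- c(betas, BETA_FLOOR); avg_losses <- c(avg_losses, Lbar)
        break
      }
      beta <- Lbar / (1 - Lbar)
      models[[length(models) + 1L]] <- model
      betas <- c(betas, beta); avg_losses <- c(avg_losses, Lbar)
      w <- w * beta^(1 - l)
      w <- w / sum(w)
      if (keep_weight_history) w_history[[t]] <- w
    }
    structure(list(models = models, betas = betas,
                   weight_history = w_history,
                   weights = log(1 / betas), avg_losses = avg_losses,
                   family = base_family, n_estimators = n_estimators,
                   aggregation = aggregation,
                   base_hyperparams = base_hyperparams,
                   features = names(X), seed = as.integer(seed)),
              class = "boost_ensemble")
  })
}

base_prediction_matrix <- function(ensemble, X) {
  vapply(ensemble$models, function(m) predict_base(m, X),
         numeric(nrow(as.data.frame(X))))
}

## Smallest prediction at which the cumulative sorted weight reaches half
## the total; vectorised over rows of the prediction matrix.
weighted_median_rows <- function(P, w) {
  if (is.null(dim(P))) P <- matrix(P, ncol = length(w))
  half <- sum(w) / 2
  apply(P, 1L, function(row) {
    o <- order(row)
    row[o[which(cumsum(w[o]) >= half)[1L]]]
  })
}

#' Predict from a boosted ensemble
#'
#' `weighted_average` returns sum_t w_t yhat_t / sum_t w_t;
#' `weighted_median` returns the smallest base prediction at which the
#' cumulative sorted confidence weight reaches half the total.
#'
#' @param ensemble a `boost_ensemble`.
#' @param X feature rows to predict.
#' @param mode aggregation mode; defaults to the ensemble's fitted mode.
#' @export
predict_ensemble <- function(ensemble, X,
                             mode = c("weighted_average", "weighted_median")) {
  stopifnot(inherits(ensemble, "boost_ensemble"))
  if (length(ensemble$models) == 0L) stop_ff("empty ensemble")
  mode <- if (missing(mode)) ensemble$aggregation else match.arg(mode)
  P <- base_prediction_matrix(ensemble, X)
  if (is.null(dim(P))) P <- matrix(P, ncol = length(ensemble$models))
  w <- ensemble$weights
  if (mode == "weighted_average") as.numeric(P %*% w / sum(w))
  else weighted_median_rows(P, w)
}

#' @export
predict.boost_ensemble <- function(object, newdata, ...) predict_ensemble(object, newdata, ...)

#' Prefix-ensemble scores by estimator count
#'
#' R^2 of the ensemble truncated to its first t base models, for
#' t = 1..T — the estimator-count diagnostic curve.
#'
#' @param ensemble a `boost_ensemble`.
#' @param X feature rows.
#' @param y reference targets.
#' @param mode aggregation mode (defaults to the ensemble's).
#' @return numeric vector of length T.
#' @export
staged_scores <- function(ensemble, X, y,
                          mode = c("weighted_average", "weighted_median")) {
  stopifnot(inherits(ensemble, "boost_ensemble"))
  mode <- if (missing(mode)) ensemble$aggregation else match.arg(mode)
  P <- base_prediction_matrix(ensemble, X)
  if (is.null(dim(P))) P <- matrix(P, ncol = length(ensemble$models))
  w <- ensemble$weights
  Tn <- ncol(P)
  if (mode == "weighted_average") {
    num <- t(apply(sweep(P, 2L, w, "*"), 1L, cumsum))
    if (Tn == 1L) num <- matrix(num, ncol = 1L)
    den <- cumsum(w)
    vapply(seq_len(Tn), function(t) r2_score(y, num[, t] / den[t]), numeric(1))
  } else {
    vapply(seq_len(Tn), function(t)
      r2_score(y, weighted_median_rows(P[, seq_len(t), drop = FALSE], w[seq_len(t)])),
      numeric(1))
  }
}
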