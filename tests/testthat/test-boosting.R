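## A constant-prediction ensemble built by hand, for aggregation tests.
constant_ensemble <- function(values, weights) {
  models <- lapply(values, function(v)
    structure(list(constant = v, fit = NULL, features = "x", max_depth = 0L),
              class = "cart_model"))
  betas <- exp(-weights)
  structure(list(models = models, betas = betas, weights = weights,
                 avg_losses = rep(NA_real_, length(values)), family = "tree",
                 n_estimators = length(values), aggregation = "weighted_average",
                 base_hyperparams = list(), features = "x", seed = 1L),
            class = "boost_ensemble")
}

test_that("a single-round ensemble equals its base model", {
  d <- step_data()
  ens <- fit_adaboost(d["x"], d$y, "tree", list(max_depth = 4L),
                      n_estimators = 1L, seed = 1L)
  base <- fit_tree(d["x"], d$y, max_depth = 4L)
  q <- data.frame(x = seq(0, 4, by = 0.21))
  expect_equal(predict_ensemble(ens, q), predict_tree(base, q))
  expect_equal(predict_ensemble(ens, q, mode = "weighted_median"),
               predict_tree(base, q))
})

test_that("boosting stops after a perfect first fit", {
  d <- step_data()
  ens <- fit_adaboost(d["x"], d$y, "tree", list(max_depth = 2L),
                      n_estimators = 25L, seed = 2L)
  expect_length(ens$models, 1L)          # depth-2 tree fits the step exactly
  expect_true(all(is.finite(ens$weights)) && all(ens$weights > 0))
})

test_that("a useless first learner raises the no-better-than-random error", {
  ## a depth-0 stump on balanced 0/1 targets has every normalized loss equal
  ## to 1, so the round-1 average loss is 1 >= 1/2
  X <- data.frame(x = seq_len(40))
  y <- rep(c(0, 1), 20)
  expect_error(fit_adaboost(X, y, "tree", list(max_depth = 0L), n_estimators = 5L),
               "no better than random")
})

test_that("round-1 weight updates match a hand-executed AdaBoost.R2 trace", {
  ## 6 points, depth-1 stumps; the hand trace recomputes every quantity of
  ## the update rule from the round-1 stump predictions
  X <- data.frame(x = c(0, 1, 2, 3, 4, 5))
  y <- c(0, 0.1, 0, 1, 0.9, 1.4)
  ens <- fit_adaboost(X, y, "tree", list(max_depth = 1L), n_estimators = 2L,
                      seed = 4L, keep_weight_history = TRUE)
  pred1 <- predict_tree(ens$models[[1]], X)
  err <- abs(pred1 - y)
  l <- err / max(err)
  Lbar <- sum(rep(1 / 6, 6) * l)
  beta <- Lbar / (1 - Lbar)
  w_hand <- rep(1 / 6, 6) * beta^(1 - l)
  w_hand <- w_hand / sum(w_hand)
  expect_equal(ens$avg_losses[1], Lbar, tolerance = 1e-12)
  expect_equal(ens$betas[1], beta, tolerance = 1e-12)
  expect_equal(ens$weight_history[[1]], w_hand, tolerance = 1e-10)
})

test_that("sample weights remain a probability vector and focus on hard rows", {
  set.seed(5)
  X <- data.frame(x = runif(30))
  y <- sin(6 * X$x) + rnorm(30, sd = 0.05)
  ens <- fit_adaboost(X, y, "tree", list(max_depth = 1L), n_estimators = 6L,
                      seed = 6L, keep_weight_history = TRUE)
  for (w in ens$weight_history) expect_equal(sum(w), 1, tolerance = 1e-12)
  ## rows with larger round-1 loss gain strictly larger relative weight
  pred1 <- predict_tree(ens$models[[1]], X)
  l <- abs(pred1 - y) / max(abs(pred1 - y))
  w1 <- ens$weight_history[[1]]
  hi <- which.max(l); lo <- which.min(l)
  expect_gt(w1[hi] / (1 / 30), w1[lo] / (1 / 30))
})

test_that("weighted average and median aggregate constant models correctly", {
  ens <- constant_ensemble(c(1, 2, 10), weights = c(1, 1, 1))
  q <- data.frame(x = c(0, 5))
  expect_equal(predict_ensemble(ens, q, mode = "weighted_average"),
               rep(13 / 3, 2))
  expect_equal(predict_ensemble(ens, q, mode = "weighted_median"), rep(2, 2))
  ## all models identical -> both modes return that model
  same <- constant_ensemble(c(7, 7, 7), weights = c(0.2, 1, 3))
  expect_equal(predict_ensemble(same, q, mode = "weighted_average"), rep(7, 2))
  expect_equal(predict_ensemble(same, q, mode = "weighted_median"), rep(7, 2))
  expect_error(predict_ensemble(constant_ensemble(numeric(0), numeric(0)), q),
               "empty ensemble")
})

test_that("the weighted median matches a brute-force cumulative-weight scan", {
  set.seed(7)
  for (rep_i in 1:20) {
    k <- sample(2:6, 1)
    vals <- rnorm(k)
    w <- runif(k, 0.1, 2)
    ens <- constant_ensemble(vals, w)
    got <- predict_ensemble(ens, data.frame(x = 0), mode = "weighted_median")
    expect_identical(got, brute_force_weighted_median(vals, w))
  }
})

test_that("increasing one model's prediction never decreases the weighted median", {
  set.seed(8)
  for (rep_i in 1:10) {
    vals <- rnorm(5); w <- runif(5, 0.1, 1)
    m1 <- brute_force_weighted_median(vals, w)
    j <- sample(5, 1)
    vals2 <- vals; vals2[j] <- vals2[j] + abs(rnorm(1))
    expect_gte(brute_force_weighted_median(vals2, w), m1)
  }
})

test_that("staged scores end at the full-ensemble score and start at the base's", {
  set.seed(9)
  X <- data.frame(x = runif(60), z = runif(60))
  y <- X$x^2 + 0.3 * sin(8 * X$z) + rnorm(60, sd = 0.02)
  ens <- fit_adaboost(X, y, "tree", list(max_depth = 2L), n_estimators = 8L,
                      seed = 10L)
  Xq <- data.frame(x = runif(40), z = runif(40))
  yq <- Xq$x^2 + 0.3 * sin(8 * Xq$z)
  ss <- staged_scores(ens, Xq, yq)
  expect_length(ss, length(ens$models))
  expect_equal(ss[length(ss)], r2_score(yq, predict_ensemble(ens, Xq)))
  base1 <- predict_tree(ens$models[[1]], Xq)
  expect_equal(ss[1], r2_score(yq, base1))
})

test_that("boosting KNN and MLP bases uses weighted bootstrap resampling deterministically", {
  set.seed(11)
  X <- data.frame(x = runif(50), z = runif(50))
  y <- 2 * X$x + X$z
  e1 <- fit_adaboost(X, y, "knn", list(k = 3L), n_estimators = 3L, seed = 12L)
  e2 <- fit_adaboost(X, y, "knn", list(k = 3L), n_estimators = 3L, seed = 12L)
  q <- data.frame(x = runif(10), z = runif(10))
  expect_identical(predict_ensemble(e1, q), predict_ensemble(e2, q))
  em <- fit_adaboost(X, y, "mlp", list(hidden = c(8L), epochs = 30L),
                     n_estimators = 2L, seed = 13L)
  expect_true(all(is.finite(predict_ensemble(em, q))))
})
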