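test_that("a depth-0 tree is a single leaf predicting the global mean", {
  d <- data.frame(x = 1:6)
  m <- fit_tree(d, c(1, 2, 3, 4, 5, 6), max_depth = 0L)
  expect_equal(predict_tree(m, data.frame(x = c(-10, 100))), c(3.5, 3.5))
})

test_that("a depth-1 tree finds the exact split of a two-level step", {
  X <- data.frame(x = c(0, 1, 2, 3))
  y <- c(0, 0, 1, 1)
  m <- fit_tree(X, y, max_depth = 1L)
  pred <- predict_tree(m, X)
  expect_equal(pred, y)                     # zero training SSE at depth 1
  ## the split threshold lies strictly between the straddled values 1 and 2
  expect_equal(predict_tree(m, data.frame(x = c(-2, 1))), c(0, 0))
  expect_equal(predict_tree(m, data.frame(x = c(2, 9))), c(1, 1))
})

test_that("the root split matches brute-force enumeration on random data", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- data.frame(a = runif(50), b = runif(50))
    y <- sin(5 * X$a) + X$b^2 + rnorm(50, sd = 0.1)
    m <- fit_tree(X, y, max_depth = 1L)
    oracle <- brute_force_best_split(X, y)
    pred <- predict_tree(m, X)
    groups <- split(seq_len(50), pred)
    sse <- sum(vapply(groups, function(g) sum((y[g] - mean(y[g]))^2), numeric(1)))
    expect_equal(sse, oracle$sse, tolerance = 1e-10)
    expect_true(setequal(which(oracle$left), groups[[1]]) ||
                setequal(which(oracle$left), groups[[2]]))
  }
})

test_that("tree predictions are piecewise constant and error on missing features", {
  d <- step_data()
  m <- fit_tree(d["x"], d$y, max_depth = 3L)
  expect_equal(predict_tree(m, data.frame(x = c(0.5, 0.51))),
               predict_tree(m, data.frame(x = c(0.5, 0.5))))
  expect_error(predict_tree(m, data.frame(z = 1)), "features")
  ## constant targets give a constant prediction
  mc <- fit_tree(d["x"], rep(2.5, nrow(d)), max_depth = 4L)
  expect_equal(predict_tree(mc, d["x"]), rep(2.5, nrow(d)))
})

test_that("tree training SSE is non-increasing in max_depth", {
  set.seed(10)
  X <- data.frame(a = runif(80), b = runif(80))
  y <- X$a * 3 + cos(7 * X$b)
  sse <- sapply(0:6, function(d) {
    m <- fit_tree(X, y, max_depth = d)
    sum((y - predict_tree(m, X))^2)
  })
  expect_true(all(diff(sse) <= 1e-12))
})

test_that("Euclidean distance matches the 3-4-5 triangle", {
  expect_identical(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(c(0, 0), c(1, 2, 3)), "equal dimension")
})

test_that("KNN returns the training target at a training point and matches brute force", {
  set.seed(3)
  X <- matrix(runif(200), 100, 2)
  y <- rnorm(100)
  expect_equal(knn_predict(X, y, X[17, , drop = FALSE], k = 1L), y[17])
  for (k in c(1L, 2L, 5L)) {
    q <- matrix(runif(40), 20, 2)
    expect_equal(knn_predict(X, y, q, k), brute_force_knn(X, y, q, k))
  }
  expect_error(knn_predict(X[0, , drop = FALSE], numeric(0), X[1, , drop = FALSE], 1L),
               "empty training set")
  expect_error(knn_predict(X, y, matrix(1, 1, 3), 2L), "features")
  expect_error(knn_predict(X, y, X[1, , drop = FALSE], 101L), "k must lie")
})

test_that("KNN distance ties are broken by the lowest training-row index", {
  X <- matrix(c(0, 2, 4), 3, 1)   # query 1 is equidistant from rows 1 and 2
  y <- c(10, 20, 30)
  expect_equal(knn_predict(X, y, matrix(1, 1, 1), k = 1L), 10)
  expect_equal(knn_predict(X, y, matrix(3, 1, 1), k = 1L), 20)
})

test_that("KNN with k = n predicts the global training mean everywhere", {
  set.seed(5)
  X <- matrix(runif(60), 30, 2); y <- runif(30)
  q <- matrix(runif(10), 5, 2)
  expect_equal(knn_predict(X, y, q, k = 30L), rep(mean(y), 5))
})

test_that("the MLP forward pass composes affine maps and activations", {
  ## zero weights -> output equals the output bias
  m <- list(W = list(matrix(0, 2, 3), matrix(0, 3, 1)),
            b = list(rep(0, 3), 0.7), activation = "relu")
  expect_equal(mlp_forward(m, matrix(c(1, -2), 1, 2)), 0.7)
  ## identity activation, one hidden layer -> affine in x
  set.seed(2)
  W1 <- matrix(rnorm(6), 2, 3); W2 <- matrix(rnorm(3), 3, 1)
  b1 <- rnorm(3); b2 <- 0.3
  mi <- list(W = list(W1, W2), b = list(b1, b2), activation = "identity")
  x <- matrix(rnorm(2), 1, 2)
  expect_equal(mlp_forward(mi, x), as.numeric((x %*% W1 + b1) %*% W2) + 0.3)
  ## hand-traced ReLU 2-2-1 net, weights 1, biases 0, input (1, -1):
  ## hidden pre-activation (0, 0) -> ReLU (0, 0) -> output 0
  mr <- list(W = list(matrix(1, 2, 2), matrix(1, 2, 1)),
             b = list(c(0, 0), 0), activation = "relu")
  expect_equal(mlp_forward(mr, matrix(c(1, -1), 1, 2)), 0)
  expect_error(mlp_forward(mr, matrix(1, 1, 3)), "features")
})

test_that("MLP training recovers an affine map and reduces the loss", {
  set.seed(6)
  X <- matrix(runif(600), 300, 2)
  y <- 2 * X[, 1] - 0.5 * X[, 2] + 0.1 + rnorm(300, sd = 0.01)
  m <- fit_mlp(X, y, hidden = c(16L, 8L), epochs = 200L, batch_size = 64L, seed = 4L)
  expect_lte(m$loss_final, m$loss_initial)
  Xh <- matrix(runif(200), 100, 2)
  yh <- 2 * Xh[, 1] - 0.5 * Xh[, 2] + 0.1
  expect_gte(r2_score(yh, mlp_forward(m, Xh)), 0.99)
})

test_that("MLP training is deterministic given the seed and handles constants", {
  set.seed(7)
  X <- matrix(runif(100), 50, 2)
  y <- sin(3 * X[, 1])
  m1 <- fit_mlp(X, y, hidden = c(8L), epochs = 30L, seed = 11L)
  m2 <- fit_mlp(X, y, hidden = c(8L), epochs = 30L, seed = 11L)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  mc <- fit_mlp(X, rep(0.7, 50), hidden = c(8L), epochs = 3000L,
                learning_rate = 5e-3, batch_size = 8L, seed = 2L)
  expect_lt(max(abs(mlp_forward(mc, X) - 0.7)), 1e-3)
})

test_that("an MLP with no hidden layers degenerates to affine regression", {
  set.seed(9)
  X <- matrix(runif(400), 200, 2)
  y <- 1.5 * X[, 1] + 0.25 * X[, 2] - 0.2
  m <- fit_mlp(X, y, hidden = integer(0), epochs = 500L, batch_size = 64L,
               learning_rate = 2e-2, seed = 3L)
  expect_length(m$W, 1L)
  co <- c(m$W[[1]])
  expect_equal(co, c(1.5, 0.25), tolerance = 0.05)
  expect_equal(m$b[[1]], -0.2, tolerance = 0.02)
})
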