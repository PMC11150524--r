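#' Fit a CART regression tree
#'
#' Greedy binary CART with variance-reduction (summed squared error)
#' splitting, grown by rpart with all pruning disabled (`cp = 0`), a depth
#' cap and a minimum leaf size. Leaf values are (weighted) means of the
#' training targets routed to the leaf. `max_depth = 0` yields a single
#' leaf predicting the global mean.
#'
#' @param X data.frame or matrix of numeric features.
#' @param y numeric targets.
#' @param max_depth maximum root-to-leaf path length (>= 0).
#' @param min_samples_leaf minimum rows per leaf.
#' @param weights optional nonnegative case weights.
#' @return object of class `cart_model`.
#' @export
fit_tree <- function(X, y, max_depth = 8L, min_samples_leaf = 1L, weights = NULL) {
  X <- as.data.frame(X)
  if (nrow(X) < 1L || length(y) != nrow(X)) stop_ff("empty input or X/y length mismatch")
  if (max_depth < 0L) stop_ff("max_depth must be >= 0")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (max_depth == 0L || nrow(X) < 2L) {
    return(structure(list(constant = sum(weights * y) / sum(weights),
                          fit = NULL, features = names(X),
                          max_depth = as.integer(max_depth)),
                     class = "cart_model"))
  }
  d <- X; d$.y <- y
  fit <- rpart::rpart(.y ~ ., data = d, weights = weights, method = "anova",
                      control = rpart::rpart.control(
                        cp = 0, xval = 0L, maxdepth = as.integer(max_depth),
                        minsplit = max(2L, 2L * as.integer(min_samples_leaf)),
                        minbucket = as.integer(min_samples_leaf),
                        maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L))
  structure(list(constant = NULL, fit = fit, features = names(X),
                 max_depth = as.integer(max_depth)),
            class = "cart_model")
}

#' Predict from a CART regression tree
#'
#' Routes each row through the fitted threshold comparisons and returns the
#' leaf value; predictions are piecewise constant over the leaf cells.
#'
#' @param model a `cart_model`.
#' @param X data with the training feature columns.
#' @export
predict_tree <- function(model, X) {
  stopifnot(inherits(model, "cart_model"))
  X <- as.data.frame(X)
  if (!all(model$features %in% names(X)))
    stop_ff("prediction features do not match training features")
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  as.numeric(predict(model$fit, newdata = X[model$features]))
}

#' @export
predict.cart_model <- function(object, newdata, ...) predict_tree(object, newdata)

#' K-nearest-neighbour regression
#'
#' Predicts each query as the mean target of its `k` nearest training rows
#' under the Euclidean distance D(X, Y) = sqrt(sum_i (X_i - Y_i)^2); exact
#' distance ties are broken in favour of the lowest training-row index.
#'
#' @param train_X matrix/data.frame of training features.
#' @param train_y numeric training targets.
#' @param query matrix/data.frame of query rows.
#' @param k neighbourhood size, 1 <= k <= nrow(train_X).
#' @export
knn_predict <- function(train_X, train_y, query, k = 2L) {
  train_X <- as.matrix(train_X); query <- as.matrix(query)
  storage.mode(train_X) <- "double"; storage.mode(query) <- "double"
  n <- nrow(train_X)
  if (n < 1L) stop_ff("empty training set")
  if (length(train_y) != n) stop_ff("train_X/train_y length mismatch")
  if (ncol(query) != ncol(train_X))
    stop_ff("query has %d features, training data has %d", ncol(query), ncol(train_X))
  k <- as.integer(k)
  if (k < 1L || k > n) stop_ff("k must lie in [1, %d]", n)
  knn_predict_cpp(train_X, as.numeric(train_y), query, k)
}

#' Euclidean distance between two points
#'
#' @param a,b numeric vectors of equal length.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop_ff("points must have equal dimension")
  sqrt(sum((a - b)^2))
}

mlp_act <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
         tanh = list(f = base::tanh, df = function(z) 1 - tanh(z)^2),
         identity = list(f = identity, df = function(z) z * 0 + 1),
         stop_ff("unknown activation '%s'", name))
}

mlp_init <- function(dims, activation) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sdv <- if (activation == "relu") sqrt(2 / dims[l]) else sqrt(1 / dims[l])
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sdv), dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

#' Forward pass of a multilayer perceptron
#'
#' Composition of affine maps and activations,
#' y = W^(L) f(W^(L-1) ... f(W^(1) x + b^(1)) ... + b^(L-1)) + b^(L),
#' with a linear output layer (regression).
#'
#' @param model an `mlp_model` from [fit_mlp()] (or a bare list with `W`,
#'   `b`, `activation`).
#' @param X matrix/data.frame of inputs, one row per sample.
#' @return numeric predictions.
#' @export
mlp_forward <- function(model, X) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  L <- length(model$W)
  if (ncol(X) != nrow(model$W[[1L]]))
    stop_ff("input has %d features, network expects %d", ncol(X), nrow(model$W[[1L]]))
  act <- mlp_act(model$activation %||% "relu")
  A <- X
  for (l in seq_len(L - 1L))
    A <- act$f(sweep(A %*% model$W[[l]], 2L, model$b[[l]], "+"))
  as.numeric(sweep(A %*% model$W[[L]], 2L, model$b[[L]], "+"))
}

#' Train a multilayer perceptron regressor
#'
#' Feedforward network with ReLU hidden layers and a linear output, trained
#' by mini-batch Adam on the mean-squared-error loss with seeded (He)
#' initialization. Training is deterministic given `seed`.
#'
#' @param X matrix/data.frame of features.
#' @param y numeric targets.
#' @param hidden integer vector of hidden-layer widths.
#' @param activation hidden activation (`"relu"`, `"tanh"`, `"identity"`).
#' @param learning_rate Adam step size (eta).
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed integer RNG seed.
#' @return object of class `mlp_model` carrying the layer weight matrices
#'   `W`, bias vectors `b`, and the initial/final training loss.
#' @export
fit_mlp <- function(X, y, hidden = c(66L, 29L), activation = "relu",
                    learning_rate = 2e-3, epochs = 200L, batch_size = 512L,
                    seed = 1L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop_ff("fit_mlp needs at least 2 samples")
  dims <- c(ncol(X), as.integer(hidden), 1L)
  act <- mlp_act(activation)
  L <- length(dims) - 1L
  with_seed(seed, {
    par <- mlp_init(dims, activation)
    W <- par$W; b <- par$b
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; it <- 0L
    full_loss <- function() {
      pred <- mlp_forward(list(W = W, b = b, activation = activation), X)
      mean((pred - y)^2)
    }
    loss0 <- full_loss()
    for (ep in seq_len(as.integer(epochs))) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        m <- length(idx)
        ## forward, caching pre-activations
        A <- vector("list", L + 1L); Z <- vector("list", L)
        A[[1L]] <- X[idx, , drop = FALSE]
        for (l in seq_len(L)) {
          Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
          A[[l + 1L]] <- if (l < L) act$f(Z[[l]]) else Z[[l]]
        }
        ## backward
        delta <- 2 * (A[[L + 1L]] - y[idx]) / m
        it <- it + 1L
        corr1 <- 1 - beta1^it; corr2 <- 1 - beta2^it
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(W[[l]])) * act$df(Z[[l - 1L]])
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    loss1 <- full_loss()
    if (!is.finite(loss1)) stop_ff("MLP training produced a non-finite loss")
    structure(list(W = W, b = b, activation = activation, hidden = dims[-c(1, L + 1L)],
                   learning_rate = learning_rate, epochs = as.integer(epochs),
                   batch_size = as.integer(batch_size), seed = as.integer(seed),
                   loss_initial = loss0, loss_final = loss1),
              class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) mlp_forward(object, newdata)
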