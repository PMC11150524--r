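## Small shared fixtures, all generated in code.

## A coarse channel solve reused by several tests (zero magnetic force).
.fixture_env <- new.env(parent = emptyenv())

small_channel_field <- function() {
  if (is.null(.fixture_env$field)) {
    grid <- build_grid(grid_spec(nx = 61L, ny = 17L))
    .fixture_env$grid <- grid
    .fixture_env$field <- solve_flow(grid)
  }
  list(grid = .fixture_env$grid, field = .fixture_env$field)
}

## 100-point unit cluster plus one planted far outlier (last row).
planted_outlier_table <- function(seed = 1L) {
  set.seed(seed)
  d <- data.frame(a = runif(100), b = runif(100))
  rbind(d, data.frame(a = 10, b = 10))
}

## Data a depth-1 regression tree can fit exactly.
step_data <- function(n = 60L, seed = 2L) {
  set.seed(seed)
  x <- runif(n, 0, 4)
  data.frame(x = x, y = ifelse(x < 2, 0, 1))
}

## Brute-force best single CART split by summed squared error of child means.
brute_force_best_split <- function(X, y) {
  X <- as.matrix(X)
  best <- list(sse = Inf)
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    thr <- (vals[-1] + vals[-length(vals)]) / 2
    for (s in thr) {
      left <- X[, j] <= s
      if (!any(left) || all(left)) next
      sse <- sum((y[left] - mean(y[left]))^2) + sum((y[!left] - mean(y[!left]))^2)
      if (sse < best$sse) best <- list(sse = sse, feature = j, threshold = s, left = left)
    }
  }
  best
}

## Brute-force KNN regression with lowest-index tie-breaking.
brute_force_knn <- function(train_X, train_y, query, k) {
  train_X <- as.matrix(train_X); query <- as.matrix(query)
  apply(query, 1L, function(q) {
    d <- sqrt(colSums((t(train_X) - q)^2))
    o <- order(d, seq_along(d))
    mean(train_y[o[seq_len(k)]])
  })
}

## Brute-force weighted median: smallest value whose cumulative sorted
## weight reaches half the total.
brute_force_weighted_median <- function(values, weights) {
  o <- order(values)
  values[o][which(cumsum(weights[o]) >= sum(weights) / 2)[1L]]
}
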