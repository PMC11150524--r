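#' Isolation-forest configuration
#'
#' @param n_trees number of isolation trees.
#' @param subsample_size rows sampled (without replacement) per tree (psi).
#' @param score_threshold anomaly-score cutoff in (0, 1); rows scoring above
#'   it are treated as outliers.
#' @param seed integer RNG seed.
#' @export
iforest_config <- function(n_trees = 100L, subsample_size = 256L,
                           score_threshold = 0.6, seed = 1L) {
  n_trees <- as.integer(n_trees)
  subsample_size <- as.integer(subsample_size)
  if (n_trees < 1L) stop_ff("n_trees must be >= 1")
  if (subsample_size < 2L) stop_ff("subsample_size must be >= 2")
  if (score_threshold <= 0 || score_threshold > 1)
    stop_ff("score_threshold must lie in (0, 1]")
  structure(list(n_trees = n_trees, subsample_size = subsample_size,
                 score_threshold = score_threshold, seed = as.integer(seed)),
            class = "iforest_config")
}

## Average unsuccessful-search path length in a BST of n points:
## c(n) = 2 H(n-1) - 2 (n-1)/n, with H the harmonic number (exact).
avg_path_length <- function(n) {
  out <- numeric(length(n))
  big <- n > 2L
  out[n == 2L] <- 1
  if (any(big)) {
    m <- n[big]
    H <- log(m - 1) + 0.5772156649015329 + 1 / (2 * (m - 1))  # H(m-1)
    exact <- m <= 256L
    if (any(exact)) {
      Hc <- cumsum(1 / seq_len(255))
      H[exact] <- Hc[m[exact] - 1L]
    }
    out[big] <- 2 * H - 2 * (m - 1) / m
  }
  out
}

## Grow one isolation tree on `X[rows, ]` up to `limit` levels.
grow_itree <- function(X, rows, depth, limit) {
  n <- length(rows)
  if (n <= 1L || depth >= limit)
    return(list(external = TRUE, size = n))
  q <- sample.int(ncol(X), 1L)
  lo <- min(X[rows, q]); hi <- max(X[rows, q])
  if (lo == hi) return(list(external = TRUE, size = n))
  split <- runif(1L, lo, hi)
  left <- rows[X[rows, q] < split]
  right <- rows[X[rows, q] >= split]
  list(external = FALSE, feature = q, split = split,
       left = grow_itree(X, left, depth + 1L, limit),
       right = grow_itree(X, right, depth + 1L, limit))
}

## Vectorised path length of every row of X through one tree.
itree_paths <- function(node, X, rows, depth, out) {
  if (node$external) {
    out[rows] <- depth + if (node$size > 1L) avg_path_length(node$size) else 0
    return(out)
  }
  go_left <- X[rows, node$feature] < node$split
  out <- itree_paths(node$left, X, rows[go_left], depth + 1, out)
  itree_paths(node$right, X, rows[!go_left], depth + 1, out)
}

#' Isolation-forest anomaly scores
#'
#' Scores each row by s(x) = 2^(-E\[h(x)\]/c(psi)), where E\[h\] is the mean
#' path length of the row over the ensemble of random axis-parallel
#' isolation trees and c(psi) the average BST path length at the subsample
#' size. Scores lie in (0, 1\]; isolated (anomalous) rows score high.
#'
#' @param table data.frame or matrix of numeric columns.
#' @param cfg an [iforest_config()].
#' @return numeric vector of per-row scores.
#' @export
isolation_scores <- function(table, cfg = iforest_config()) {
  stopifnot(inherits(cfg, "iforest_config"))
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2L) stop_ff("isolation_scores needs at least 2 rows")
  if (ncol(X) < 1L) stop_ff("isolation_scores needs at least 1 numeric column")
  if (cfg$subsample_size > n)
    stop_ff("subsample_size (%d) exceeds the number of rows (%d)",
            cfg$subsample_size, n)
  psi <- cfg$subsample_size
  limit <- ceiling(log2(psi))
  with_seed(cfg$seed, {
    total <- numeric(n)
    for (t in seq_len(cfg$n_trees)) {
      rows <- sample.int(n, psi)
      tree <- grow_itree(X, rows, 0L, limit)
      total <- total + itree_paths(tree, X, seq_len(n), 0, numeric(n))
    }
    2^(-(total / cfg$n_trees) / avg_path_length(psi))
  })
}

#' Remove outliers by isolation-forest score
#'
#' @param table data.frame of numeric columns.
#' @param cfg an [iforest_config()]; rows with score > `score_threshold` are
#'   dropped.
#' @return list with `kept` (row-order-preserving data.frame), `removed`
#'   (integer row ids of the input) and `scores`.
#' @export
remove_outliers <- function(table, cfg = iforest_config()) {
  s <- isolation_scores(table, cfg)
  bad <- which(s > cfg$score_threshold)
  if (length(bad) == nrow(table))
    stop_ff("score_threshold %.3f removes every row", cfg$score_threshold)
  kept <- table[setdiff(seq_len(nrow(table)), bad), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = bad, scores = s)
}

#' Fit a per-column min-max scaler
#'
#' @param table data.frame or matrix of numeric columns (typically the
#'   training split only, to avoid leakage into the test metrics).
#' @return object of class `minmax_params` with per-column `min` and `max`.
#' @export
fit_minmax <- function(table) {
  X <- as.matrix(table)
  mins <- apply(X, 2L, min); maxs <- apply(X, 2L, max)
  cons <- maxs <= mins
  if (any(cons))
    stop_ff("constant column(s) cannot be min-max scaled: %s",
            paste(colnames(X)[cons], collapse = ", "))
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' Apply a min-max scaling
#'
#' Maps each column v to (v - min)/(max - min) using parameters fitted with
#' [fit_minmax()] (training minima/maxima map to 0/1; test values may fall
#' slightly outside).
#'
#' @param table data to scale; columns must match the fitted parameters.
#' @param params a `minmax_params`.
#' @export
apply_minmax <- function(table, params) {
  stopifnot(inherits(params, "minmax_params"))
  out <- as.data.frame(table)
  for (cn in names(params$min))
    out[[cn]] <- (out[[cn]] - params$min[[cn]]) / (params$max[[cn]] - params$min[[cn]])
  out
}

#' Invert a min-max scaling
#'
#' @param scaled scaled data (or a numeric vector for a single named column
#'   via `column=`).
#' @param params a `minmax_params`.
#' @param column optional column name when `scaled` is a bare numeric vector.
#' @export
invert_minmax <- function(scaled, params, column = NULL) {
  stopifnot(inherits(params, "minmax_params"))
  if (!is.null(column)) {
    return(scaled * (params$max[[column]] - params$min[[column]]) + params$min[[column]])
  }
  out <- as.data.frame(scaled)
  for (cn in names(params$min))
    out[[cn]] <- out[[cn]] * (params$max[[cn]] - params$min[[cn]]) + params$min[[cn]]
  out
}

#' Random train/test split
#'
#' Uniform random permutation under the seed; the first floor(ratio * n)
#' permuted rows form the training set.
#'
#' @param n number of rows (or a data.frame, whose row count is used).
#' @param ratio training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return object of class `split_result` with integer `train` and `test`
#'   index vectors.
#' @export
train_test_split <- function(n, ratio = 0.8, seed = 1L) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 2L) stop_ff("need at least 2 rows to split")
  if (ratio <= 0 || ratio >= 1) stop_ff("ratio must lie in (0, 1)")
  n_train <- floor(ratio * n)
  if (n_train < 1L || n_train >= n)
    stop_ff("split leaves an empty side (n = %d, ratio = %g)", n, ratio)
  perm <- with_seed(seed, sample.int(n))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[(n_train + 1L):n]),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_result")
}
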