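#' @useDynLib ferroflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict runif rnorm sd var
#' @importFrom utils read.csv write.csv head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}

## Derive a per-stage child seed from one global seed; keeps values < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

stop_ff <- function(...) stop(sprintf(...), call. = FALSE)

as_xy_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L) stop_ff("a point must have exactly 2 coordinates")
    points <- matrix(points, 1L, 2L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_ff("points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  points
}
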