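#' Hyperparameter search space
#'
#' One row per (flattened) hyperparameter dimension. Tuple-valued
#' hyperparameters such as hidden layer sizes are flattened into one
#' dimension per element (e.g. `hidden1`, `hidden2`) and reassembled when a
#' candidate vector is decoded.
#'
#' @param name character vector of dimension names.
#' @param kind `"integer"` or `"real"` per dimension; integer dimensions are
#'   rounded after every position update.
#' @param lower,upper per-dimension bounds, `lower < upper`.
#' @return data.frame of class `search_space`.
#' @export
search_space <- function(name, kind, lower, upper) {
  stopifnot(length(name) == length(kind), length(name) == length(lower),
            length(name) == length(upper))
  if (!all(kind %in% c("integer", "real"))) stop_ff("kind must be 'integer' or 'real'")
  if (any(lower >= upper)) stop_ff("need lower < upper in every dimension")
  structure(data.frame(name = name, kind = kind, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("search_space", "data.frame"))
}

#' Swarm configuration for the bat tuner
#'
#' @param n_bats population size (>= 2).
#' @param n_iterations number of swarm iterations (>= 0).
#' @param f_min,f_max frequency range, `f_min < f_max`.
#' @param seed integer RNG seed.
#' @param local_search enable the echolocation local random walk around the
#'   best-known position (loudness/pulse-rate mechanics). The bare
#'   three-equation position update is divergent on its own (bats spiral
#'   outward and pin at the bounds), so the walk is on by default; disable
#'   it to study the raw update dynamics.
#' @param loudness acceptance loudness A in (0, 1\].
#' @param pulse_rate baseline pulse emission rate r0 in \[0, 1\].
#' @param local_scale local-walk step size, as a fraction of each
#'   dimension's range.
#' @export
swarm_config <- function(n_bats = 20L, n_iterations = 50L, f_min = 0,
                         f_max = 1.5, seed = 1L, local_search = TRUE,
                         loudness = 0.9, pulse_rate = 0.5, local_scale = 0.1) {
  n_bats <- as.integer(n_bats)
  if (n_bats < 2L) stop_ff("n_bats must be >= 2")
  if (f_min >= f_max) stop_ff("need f_min < f_max")
  structure(list(n_bats = n_bats, n_iterations = as.integer(n_iterations),
                 f_min = f_min, f_max = f_max, seed = as.integer(seed),
                 local_search = isTRUE(local_search), loudness = loudness,
                 pulse_rate = pulse_rate, local_scale = local_scale),
            class = "swarm_config")
}

clip_round <- function(pos, space) {
  pos <- pmin(pmax(pos, space$lower), space$upper)
  ints <- space$kind == "integer"
  pos[ints] <- round(pos[ints])
  pos
}

#' One bat position update
#'
#' Applies the three update equations in order, with beta drawn uniformly
#' per dimension:
#' f_i = f_min + (f_max - f_min) beta;
#' v_i = v_i + (Theta_i - Theta_best) f_i;
#' Theta_i = Theta_i + v_i.
#' The position is then clipped to the bounds and integer dimensions are
#' rounded. Uses R's current RNG stream.
#'
#' @param state list with numeric `position` and `velocity`.
#' @param best best-known position (same length).
#' @param space a [search_space()].
#' @param cfg a [swarm_config()] (frequency range).
#' @param beta optional fixed beta vector (for deterministic stepping);
#'   drawn from U(0,1) when `NULL`.
#' @return updated state with fields `position`, `velocity`, `frequency`.
#' @export
bat_step <- function(state, best, space, cfg, beta = NULL) {
  d <- length(state$position)
  if (is.null(beta)) beta <- runif(d)
  f <- cfg$f_min + (cfg$f_max - cfg$f_min) * beta
  vel <- state$velocity + (state$position - best) * f
  pos <- state$position + vel
  list(position = clip_round(pos, space), velocity = vel, frequency = f)
}

decode_theta <- function(theta, space) {
  v <- as.list(theta)
  names(v) <- space$name
  ints <- space$kind == "integer"
  v[ints] <- lapply(v[ints], as.integer)
  ## reassemble flattened tuples: hidden1, hidden2, ... -> hidden
  tup <- grep("^hidden[0-9]+$", names(v), value = TRUE)
  if (length(tup)) {
    v$hidden <- as.integer(unlist(v[tup], use.names = FALSE))
    v[tup] <- NULL
  }
  v
}

#' Cross-validated fitness of a hyperparameter vector
#'
#' k-fold cross-validated R^2 of the configured model on the supplied data,
#' deterministic given the seed. A model-fitting failure yields the -Inf
#' sentinel (with a warning) rather than an error, so a swarm can step over
#' degenerate candidates.
#'
#' @param theta named numeric vector of hyperparameters (flattened).
#' @param objective_spec list with `family` (`"tree"`, `"knn"`, `"mlp"`),
#'   optional `fixed` hyperparameters, optional `n_estimators` (> 0 boosts
#'   the base model), and `folds` (default 3).
#' @param data list with feature frame `X` and targets `y`.
#' @param seed integer RNG seed for fold assignment and stochastic fits.
#' @export
evaluate_fitness <- function(theta, objective_spec, data, seed = 1L) {
  folds <- objective_spec$folds %||% 3L
  th <- as.list(theta)
  tup <- grep("^hidden[0-9]+$", names(th), value = TRUE)
  if (length(tup)) {
    th$hidden <- as.integer(round(unlist(th[tup], use.names = FALSE)))
    th[tup] <- NULL
  }
  hp <- utils::modifyList(objective_spec$fixed %||% list(), th)
  family <- objective_spec$family
  n <- nrow(data$X)
  fold_id <- with_seed(child_seed(seed, 97L), sample(rep_len(seq_len(folds), n)))
  scores <- numeric(folds)
  out <- tryCatch({
    for (fd in seq_len(folds)) {
      tr <- fold_id != fd
      Xtr <- data$X[tr, , drop = FALSE]; ytr <- data$y[tr]
      Xte <- data$X[!tr, , drop = FALSE]; yte <- data$y[!tr]
      nest <- objective_spec$n_estimators %||% 0L
      pred <- if (nest > 0L) {
        ens <- fit_adaboost(Xtr, ytr, base_family = family,
                            base_hyperparams = hp, n_estimators = nest,
                            seed = child_seed(seed, fd))
        predict_ensemble(ens, Xte)
      } else {
        model <- with_seed(child_seed(seed, fd),
                           fit_base(family, Xtr, ytr, hp, rep(1 / sum(tr), sum(tr)),
                                    seed = child_seed(seed, fd)))
        predict_base(model, Xte)
      }
      scores[fd] <- r2_score(yte, pred)
    }
    mean(scores)
  }, error = function(e) {
    warning(sprintf("fitness evaluation failed (%s); returning -Inf",
                    conditionMessage(e)), call. = FALSE)
    -Inf
  })
  out
}

#' Tune hyperparameters with the bat algorithm
#'
#' Runs a swarm of candidate hyperparameter vectors over the search space,
#' maximizing `objective`. Each iteration applies the frequency/velocity/
#' position updates of [bat_step()] to every bat and, when enabled, the
#' echolocation local random walk around the best-known position with
#' loudness-gated acceptance. Returns the best-ever position, its fitness
#' and the per-iteration best-fitness trace (monotone non-decreasing).
#'
#' @param space a [search_space()].
#' @param cfg a [swarm_config()].
#' @param objective function taking a named numeric vector, returning a
#'   scalar fitness to maximize (may return `-Inf` for failures).
#' @return list with `best` (named numeric), `best_fitness`, and `trace`
#'   (data.frame iteration/best_fitness).
#' @export
bat_tune <- function(space, cfg, objective) {
  stopifnot(inherits(space, "search_space"), inherits(cfg, "swarm_config"))
  d <- nrow(space)
  eval_named <- function(pos) {
    names(pos) <- space$name
    objective(pos)
  }
  with_seed(cfg$seed, {
    pos <- sapply(seq_len(d), function(j) runif(cfg$n_bats, space$lower[j], space$upper[j]))
    pos <- matrix(pos, cfg$n_bats, d)
    for (i in seq_len(cfg$n_bats)) pos[i, ] <- clip_round(pos[i, ], space)
    vel <- matrix(0, cfg$n_bats, d)
    fit <- apply(pos, 1L, eval_named)
    if (all(!is.finite(fit))) stop_ff("all initial fitness evaluations failed")
    bi <- which.max(fit)
    best <- pos[bi, ]; best_fit <- fit[bi]
    trace <- data.frame(iteration = integer(0), best_fitness = numeric(0))
    if (cfg$n_iterations > 0L) {
      for (it in seq_len(cfg$n_iterations)) {
        for (i in seq_len(cfg$n_bats)) {
          st <- bat_step(list(position = pos[i, ], velocity = vel[i, ]),
                         best, space, cfg)
          cand <- st$position
          if (cfg$local_search &&
              runif(1) > cfg$pulse_rate * (1 - exp(-0.9 * it))) {
            cand <- clip_round(best + cfg$local_scale * cfg$loudness *
                                 rnorm(d) * (space$upper - space$lower), space)
          }
          fc <- eval_named(cand)
          accept <- is.finite(fc) &&
            (fc > fit[i] || (cfg$local_search && runif(1) < cfg$loudness))
          if (accept) { pos[i, ] <- cand; fit[i] <- fc }
          vel[i, ] <- st$velocity
          if (is.finite(fc) && fc > best_fit) { best <- cand; best_fit <- fc }
        }
        trace <- rbind(trace, data.frame(iteration = it, best_fitness = best_fit))
      }
    }
    names(best) <- space$name
    list(best = best, best_fitness = best_fit, trace = trace)
  })
}
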