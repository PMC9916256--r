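# Sparrow search optimisation (SSO): a population metaheuristic with three
# roles. Discoverers (the best-ranked fraction) lead the search, joiners follow
# them, and a randomly drawn set of guarders performs anti-predation
# perturbations. Minimisation over a box; positions are clipped to the bounds
# after every update and the reported best is an elitist archive.

#' SSO control parameters
#'
#' @param st Safety value in `(0.5, 1]`; discoverers explore widely while the
#'   warning value stays below it. Default 0.8.
#' @param pd Discoverer fraction in `(0, 1)`. Default 0.2.
#' @param sd Guarder fraction in `(0, 1)`. Default 0.2.
#' @param epsilon Small positive constant guarding the guarder-update
#'   denominator. Default 1e-8.
#' @return Named list of control values.
#' @export
sso_control <- function(st = 0.8, pd = 0.2, sd = 0.2, epsilon = 1e-8) {
  if (!(st > 0.5 && st <= 1)) stop_input("st must lie in (0.5, 1]")
  if (!(pd > 0 && pd < 1) || !(sd > 0 && sd < 1)) {
    stop_input("pd and sd must lie in (0, 1)")
  }
  if (epsilon <= 0) stop_input("epsilon must be positive")
  list(st = st, pd = pd, sd = sd, epsilon = epsilon)
}

check_bounds <- function(bounds, d = NULL) {
  if (is.vector(bounds) && length(bounds) == 2L) {
    bounds <- matrix(bounds, nrow = if (is.null(d)) 1L else d, ncol = 2L,
                     byrow = TRUE)
  }
  if (!is.matrix(bounds) || ncol(bounds) != 2L) {
    stop_input("bounds must be a d x 2 matrix (columns lo, hi) or a c(lo, hi) pair")
  }
  if (any(bounds[, 1L] >= bounds[, 2L])) stop_input("need lo < hi per dimension")
  if (!is.null(d) && nrow(bounds) == 1L && d > 1L) {
    bounds <- bounds[rep(1L, d), , drop = FALSE]
  }
  if (!is.null(d) && nrow(bounds) != d) {
    stop_input("bounds must have one row per dimension")
  }
  bounds
}

#' Initialise a sparrow population
#'
#' Positions are drawn uniformly inside the bounds, reproducibly by seed.
#'
#' @param np Population size (>= 4, so the role split has members).
#' @param d Search-space dimension.
#' @param bounds `d x 2` matrix of `(lo, hi)` per dimension, or a single
#'   `c(lo, hi)` pair recycled over dimensions.
#' @param seed Integer seed.
#' @return `np x d` matrix of positions.
#' @export
sso_init_population <- function(np, d, bounds, seed = 1L) {
  if (!is_count(np) || np < 4L) {
    stop_input("np must be an integer >= 4 (role split needs members)")
  }
  stopifnot(is_count(d), d >= 1)
  bounds <- check_bounds(bounds, d)
  with_seed(seed, {
    X <- matrix(stats::runif(np * d), np, d)
    sweep(sweep(X, 2L, bounds[, 2L] - bounds[, 1L], "*"), 2L,
          bounds[, 1L], "+")
  })
}

#' Discoverer position update
#'
#' For each discoverer (fitness rank `i`, best = 1): draw a warning value
#' `R2 ~ U(0, 1]`; while `R2 < ST` the position contracts as
#' `X * exp(-i / (alpha * T_max))` with `alpha ~ U(0, 1]`; otherwise the
#' sparrow relocates by a shared standard-normal step, `X + O * G` with `G`
#' the all-ones row. Results are clipped to the bounds.
#'
#' @param X `n_disc x d` matrix of discoverer positions, best-ranked first.
#' @param t_max Iteration budget `T` of the run.
#' @param control [sso_control()] list.
#' @param bounds `d x 2` bounds matrix.
#' @param draws Optional list overriding the random draws (for fixtures):
#'   `r2`, `alpha` (vectors over sparrows), `o` (vector over sparrows).
#' @return Updated, clipped position matrix.
#' @export
sso_update_discoverers <- function(X, t_max, control, bounds, draws = NULL) {
  n <- nrow(X); d <- ncol(X)
  r2 <- if (!is.null(draws$r2)) draws$r2 else stats::runif(n)
  alpha <- if (!is.null(draws$alpha)) draws$alpha else stats::runif(n)
  o <- if (!is.null(draws$o)) draws$o else stats::rnorm(n)
  for (i in seq_len(n)) {
    if (r2[i] < control$st) {
      X[i, ] <- X[i, ] * exp(-i / (alpha[i] * t_max))
    } else {
      X[i, ] <- X[i, ] + o[i] # O * G, G = ones(1, d)
    }
  }
  clip_rows(X, bounds)
}

#' Joiner position update
#'
#' Joiners carry their overall fitness rank `i` (1-based, best = 1) in a
#' population of `n` sparrows. The worse half (`i > n/2`) scatters as
#' `O * exp((Xw - X) / i^2)` elementwise around the worst position `Xw`; the
#' rest converge on the best discoverer position `Xb` as
#' `Xb + |X - Xb| . B . G` with `B` a random sign per dimension.
#'
#' @param X `n_join x d` matrix of joiner positions.
#' @param ranks Integer vector of overall fitness ranks for each row.
#' @param n Population size.
#' @param xb Best discoverer position (length `d`).
#' @param xw Worst position in the population (length `d`).
#' @param bounds `d x 2` bounds matrix.
#' @param draws Optional overrides: `o` (vector over sparrows), `b` (matrix of
#'   signs, `n_join x d`).
#' @return Updated, clipped position matrix.
#' @export
sso_update_joiners <- function(X, ranks, n, xb, xw, bounds, draws = NULL) {
  nj <- nrow(X); d <- ncol(X)
  o <- if (!is.null(draws$o)) draws$o else stats::rnorm(nj)
  B <- if (!is.null(draws$b)) draws$b else
    matrix(sample(c(-1, 1), nj * d, replace = TRUE), nj, d)
  for (k in seq_len(nj)) {
    i <- ranks[k]
    if (i > n / 2) {
      X[k, ] <- o[k] * exp((xw - X[k, ]) / i^2)
    } else {
      X[k, ] <- xb + abs(X[k, ] - xb) * B[k, ]
    }
  }
  clip_rows(X, bounds)
}

#' Guarder position update
#'
#' A random subset of the population reacts to danger. A guarder whose fitness
#' is worse than the global best (`f_i > f_g`) jumps towards the best position:
#' `Xbest + beta * |X - Xbest|` with `beta` a standard-normal draw truncated to
#' `[-1, 1]`. A guarder already at the best fitness (`f_i = f_g`) moves
#' relative to the worst: `X + K * (X - Xworst) / ((f_i - f_w) + epsilon)`,
#' `K ~ U[-1, 1]`.
#'
#' @param X `n_guard x d` matrix of guarder positions.
#' @param f Fitness values of those guarders.
#' @param f_g,f_w Current best and worst fitness in the population.
#' @param xbest,xworst Global best and current worst positions (length `d`).
#' @param control [sso_control()] list.
#' @param bounds `d x 2` bounds matrix.
#' @param draws Optional overrides: `beta`, `k` (vectors over sparrows).
#' @return Updated, clipped position matrix.
#' @export
sso_update_guarders <- function(X, f, f_g, f_w, xbest, xworst, control,
                                bounds, draws = NULL) {
  ng <- nrow(X)
  beta <- if (!is.null(draws$beta)) draws$beta else
    pmin(pmax(stats::rnorm(ng), -1), 1)
  K <- if (!is.null(draws$k)) draws$k else stats::runif(ng, -1, 1)
  for (i in seq_len(ng)) {
    if (f[i] > f_g) {
      X[i, ] <- xbest + beta[i] * abs(X[i, ] - xbest)
    } else {
      X[i, ] <- X[i, ] + K[i] * (X[i, ] - xworst) /
        ((f[i] - f_w) + control$epsilon)
    }
  }
  clip_rows(X, bounds)
}

clip_rows <- function(X, bounds) {
  for (j in seq_len(ncol(X))) {
    X[, j] <- clip_to_bounds(X[, j], bounds[j, 1L], bounds[j, 2L])
  }
  X
}

#' Exact-match multilabel classifier error rate
#'
#' The fitness used for hyperparameter tuning: the percentage of samples whose
#' predicted label vector differs from the truth in any position
#' (misclassified / total * 100). A per-label Hamming variant is available for
#' sensitivity analyses.
#'
#' @param predicted,truth `N x C` binary matrices of equal shape.
#' @param hamming If `TRUE`, return the mean per-label disagreement percentage
#'   instead of the exact-match rate. Default `FALSE`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' fitness_error_rate(matrix(c(1, 0), 1), matrix(c(1, 1), 1)) # 100
fitness_error_rate <- function(predicted, truth, hamming = FALSE) {
  if (!is.matrix(predicted) || !is.matrix(truth) ||
      !identical(dim(predicted), dim(truth))) {
    stop_input("predicted and truth must be matrices of identical shape")
  }
  if (nrow(predicted) == 0L) stop_input("need at least one sample")
  if (hamming) {
    mean(predicted != truth) * 100
  } else {
    mean(rowSums(predicted != truth) > 0) * 100
  }
}

#' Minimise an objective with sparrow search optimisation
#'
#' Runs the discoverer/joiner/guarder updates for `t_max` iterations on a
#' population of `np` sparrows. The global best is kept in an elitist archive,
#' so the reported best-so-far fitness is non-increasing even when the whole
#' population moves away from it. Objective values that are `NaN`/`NA` are
#' treated as `+Inf` with a warning.
#'
#' @param objective Function mapping a length-`d` position to a scalar to be
#'   minimised.
#' @param bounds `d x 2` matrix of box bounds (or a `c(lo, hi)` pair with `d`
#'   given implicitly by its rows — pass a matrix for `d > 1`).
#' @param np Population size. Default 20.
#' @param t_max Iteration budget. Default 100.
#' @param control [sso_control()] list.
#' @param seed Integer seed; fixes the whole trajectory.
#' @return List with `best_position`, `best_fitness`, `trace` (data frame of
#'   `iteration`, `best_fitness`, best-so-far), `population`, `fitness`,
#'   `n_evals`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- sso_optimize(sphere, matrix(c(-5, 5), 2, 2, byrow = TRUE),
#'                     np = 10, t_max = 20, seed = 1)
#' res$best_fitness
sso_optimize <- function(objective, bounds, np = 20L, t_max = 100L,
                         control = sso_control(), seed = 1L) {
  bounds <- check_bounds(bounds)
  d <- nrow(bounds)
  if (!is_count(t_max) || t_max < 1) stop_input("t_max must be >= 1")
  eval_fit <- function(X) {
    f <- vapply(seq_len(nrow(X)), function(i) {
      v <- objective(X[i, ])
      if (length(v) != 1L) stop_input("objective must return a scalar")
      as.numeric(v)
    }, numeric(1L))
    if (any(!is.finite(f) & !is.infinite(f))) {
      warning("objective returned NaN/NA; treated as +Inf", call. = FALSE)
      f[!is.finite(f) & !is.infinite(f)] <- Inf
    }
    f
  }
  X <- sso_init_population(np, d, bounds, seed = derive_seed(seed, "init"))
  f <- eval_fit(X)
  n_evals <- np
  best_i <- which.min(f)
  xbest <- X[best_i, ]
  fbest <- f[best_i]
  trace <- numeric(t_max)
  n_disc <- ceiling(control$pd * np)
  n_guard <- ceiling(control$sd * np)
  with_seed(derive_seed(seed, "updates"), {
    for (t in seq_len(t_max)) {
      ord <- order(f)
      ranks <- integer(np); ranks[ord] <- seq_len(np)
      disc <- ord[seq_len(n_disc)]
      join <- ord[setdiff(seq_len(np), seq_len(n_disc))]
      xw <- X[ord[np], ]
      X[disc, ] <- sso_update_discoverers(X[disc, , drop = FALSE], t_max,
                                          control, bounds)
      xb <- X[disc[1L], ] # best discoverer, post-update
      if (length(join) > 0L) {
        X[join, ] <- sso_update_joiners(X[join, , drop = FALSE], ranks[join],
                                        np, xb, xw, bounds)
      }
      guard <- sample.int(np, n_guard)
      X[guard, ] <- sso_update_guarders(X[guard, , drop = FALSE], f[guard],
                                        min(f), max(f), xbest,
                                        X[which.max(f), ], control, bounds)
      f <- eval_fit(X)
      n_evals <- n_evals + np
      if (min(f) < fbest) { # elitist archive
        fbest <- min(f)
        xbest <- X[which.min(f), ]
      }
      trace[t] <- fbest
    }
  })
  list(best_position = xbest, best_fitness = fbest,
       trace = data.frame(iteration = seq_len(t_max), best_fitness = trace),
       population = X, fitness = f, n_evals = n_evals)
}

#' Hyperparameter box for MLSTM-AE tuning
#'
#' Defines the bounded real search space handed to [sso_optimize()] and how
#' each dimension decodes into a training hyperparameter: the learning rate
#' lives on a log10 scale, integer sizes are rounded, the rest are taken as-is.
#'
#' @return Data frame with columns `name`, `lo`, `hi`, `type`
#'   (`"log10"`, `"int"`, `"real"`).
#' @export
default_hyper_box <- function() {
  data.frame(
    name = c("lr", "hidden", "batch_size", "gamma", "dropout"),
    lo = c(-2.5, 8, 16, 0, 0),
    hi = c(-1.0, 32, 64, 2, 0.3),
    type = c("log10", "int", "int", "real", "real"),
    stringsAsFactors = FALSE
  )
}

#' Decode an SSO position into training hyperparameters
#'
#' @param position Numeric vector, one entry per row of `box`.
#' @param box Search-space definition from [default_hyper_box()].
#' @return Named list of decoded hyperparameter values.
#' @export
decode_hyperparams <- function(position, box = default_hyper_box()) {
  stopifnot(length(position) == nrow(box))
  vals <- lapply(seq_len(nrow(box)), function(i) {
    switch(box$type[i],
           log10 = 10^position[i],
           int = as.integer(round(position[i])),
           real = position[i])
  })
  stats::setNames(vals, box$name)
}

#' Tune MLSTM-AE hyperparameters with sparrow search
#'
#' The objective trains the model on a fixed training split (seeded by
#' `seed`, identical across fitness evaluations so the objective is
#' deterministic in the position) and returns the exact-match classifier error
#' rate on the validation split.
#'
#' @param x `N x T x d` sequence array.
#' @param y `N x C` binary label matrix.
#' @param box Hyperparameter search space ([default_hyper_box()]).
#' @param np Population size. Default 10.
#' @param t_max SSO iteration budget. Default 20.
#' @param seed Master seed (split, init, SSO draws).
#' @param epochs Training epochs per fitness evaluation (and for the refit,
#'   so the selected configuration is evaluated at the budget it will be used
#'   with). Default 6.
#' @param control [sso_control()] list.
#' @param hamming Use per-label Hamming error instead of exact match.
#' @param refit Retrain with the best hyperparameters on the identical
#'   training stream the tuner scored and return that model, so the returned
#'   fit is exactly the configuration the search selected. Default `FALSE`.
#' @return List with `hyper` (decoded best hyperparameters), `best_fitness`
#'   (validation error rate, %), `control` (the ready-to-use
#'   [mlstm_control()] list), `trace`, the raw `sso` result, and — when
#'   `refit` — `model`, the refitted `mlstm_ae`.
#' @export
tune_mlstm <- function(x, y, box = default_hyper_box(), np = 10L,
                       t_max = 20L, seed = 1L, epochs = 6L,
                       control = sso_control(), hamming = FALSE,
                       refit = FALSE) {
  check_xy(x, y)
  train_seed <- derive_seed(seed, "tune-train")
  make_ctrl <- function(hp) {
    mlstm_control(
      hidden = hp$hidden %||% 24L, lr = hp$lr %||% 0.02,
      epochs = epochs, batch_size = hp$batch_size %||% 32L,
      gamma = hp$gamma %||% 1, dropout = hp$dropout %||% 0,
      val_frac = 0.25
    )
  }
  objective <- function(pos) {
    fit <- mlstm_train(x, y, make_ctrl(decode_hyperparams(pos, box)),
                       seed = train_seed)
    p <- predict_scores(fit, x[fit$val_idx, , , drop = FALSE])
    fitness_error_rate((p >= 0.5) * 1, y[fit$val_idx, , drop = FALSE],
                       hamming = hamming)
  }
  res <- sso_optimize(objective, as.matrix(box[, c("lo", "hi")]), np = np,
                      t_max = t_max, control = control,
                      seed = derive_seed(seed, "sso"))
  hp <- decode_hyperparams(res$best_position, box)
  best_ctrl <- make_ctrl(hp)
  out <- list(hyper = hp, best_fitness = res$best_fitness,
              control = best_ctrl, train_seed = train_seed,
              trace = res$trace, sso = res)
  if (refit) out$model <- mlstm_train(x, y, best_ctrl, seed = train_seed)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
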