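#' Particle swarm configuration
#'
#' Hyperparameters of the global-best particle swarm maximiser.  Defaults
#' are the published calibration for the sensory-surface validation: swarm
#' of 10, 40 iterations, cognitive and social coefficients
#' \eqn{c_1 = c_2 = 0.10}, inertia weight decaying linearly from 0.90 in
#' the first iteration to 0.30 in the last, 30 independent runs.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param iterations Number of velocity/position updates per run (>= 1).
#' @param c1,c2 Cognitive (personal-best) and social (global-best)
#'   acceleration coefficients.
#' @param w_start,w_end Inertia weight at the first and last iteration;
#'   `w_start >= w_end`.
#' @param bounds Search rectangle `list(x1 = c(lo, hi), x2 = c(lo, hi))`
#'   in natural units; positions are clamped to it component-wise.
#' @param n_runs Independent restarts for [multi_run()].
#' @param seed Master integer seed; run `k` uses `seed + k - 1`.
#' @param velocity_clamp Optional fraction of each dimension's range used
#'   as a symmetric speed limit; `NULL` (default) leaves velocities free,
#'   matching a position-clamp-only scheme.
#' @param v0_frac Initial velocities are drawn uniformly in
#'   `+/- v0_frac * range` per dimension.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(swarm_size = 10, iterations = 40, c1 = 0.10,
                         c2 = 0.10, w_start = 0.90, w_end = 0.30,
                         bounds = reproduction_bounds(), n_runs = 30,
                         seed = 1L, velocity_clamp = NULL, v0_frac = 0.10) {
  stopifnot(swarm_size >= 2, iterations >= 1, w_start >= w_end,
            c1 >= 0, c2 >= 0, n_runs >= 1, v0_frac >= 0)
  b <- .as_bounds(bounds)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 c1 = c1, c2 = c2, w_start = w_start, w_end = w_end,
                 bounds = b, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), velocity_clamp = velocity_clamp,
                 v0_frac = v0_frac),
            class = "swarm_config")
}

#' Inertia weight at a given iteration
#'
#' Linear decay over the schedule: at 0-based iteration `t`,
#' `w_start + (w_end - w_start) * t / (iterations - 1)`, so the first
#' iteration uses `w_start` and the last uses `w_end` exactly.  A
#' single-iteration schedule uses `w_start`.
#'
#' @param t 0-based iteration index, `0 <= t < iterations`.
#' @param config A [swarm_config()].
#' @return Scalar inertia weight.
#' @export
inertia_at <- function(t, config) {
  stopifnot(inherits(config, "swarm_config"))
  if (any(t < 0 | t >= config$iterations))
    stop("iteration index out of range [0, ", config$iterations - 1, "]")
  if (config$iterations == 1L) return(rep(config$w_start, length(t)))
  config$w_start + (config$w_end - config$w_start) * t / (config$iterations - 1)
}

#' One particle velocity/position update
#'
#' The canonical global-best update:
#' \deqn{v \gets w v + c_1 r_1 (p_i - x) + c_2 r_2 (p_g - x), \qquad
#'       x \gets x + v,}
#' with `r1`, `r2` uniform draws in \[0, 1\] (one scalar each per particle
#' per iteration, shared across dimensions).  The new position is clamped
#' to `bounds` component-wise; the velocity is left unchanged on clamp.
#'
#' @param position,velocity,pbest,gbest Numeric 2-vectors.
#' @param w,c1,c2 Scalars.
#' @param r1,r2 Scalars in \[0, 1\].
#' @param bounds Optional rectangle (see [swarm_config()]); `NULL` skips
#'   clamping.
#' @return List with updated `position` and `velocity`.
#' @examples
#' update_particle(c(140, 400), c(1, 0), pbest = c(145, 400),
#'                 gbest = c(150, 400), w = 0.9, c1 = 0.1, c2 = 0.1,
#'                 r1 = 1, r2 = 1)  # velocity (2.4, 0), position (142.4, 400)
#' @export
update_particle <- function(position, velocity, pbest, gbest, w, c1, c2,
                            r1, r2, bounds = NULL) {
  stopifnot(r1 >= 0, r1 <= 1, r2 >= 0, r2 <= 1)
  v <- w * velocity + c1 * r1 * (pbest - position) +
       c2 * r2 * (gbest - position)
  x <- position + v
  if (!is.null(bounds)) {
    b <- .as_bounds(bounds)
    x <- pmin(pmax(x, b[, 1]), b[, 2])
  }
  list(position = x, velocity = v)
}

.objective_fn <- function(objective) {
  if (inherits(objective, "poly_surface"))
    function(x1, x2) evaluate_surface(objective, x1, x2)
  else match.fun(objective)
}

#' Maximise an objective with a single particle swarm run
#'
#' Positions are initialised uniformly inside the bounds and velocities
#' uniformly in `+/- v0_frac * range`; the swarm then iterates
#' `config$iterations` velocity/position updates with linearly decaying
#' inertia.  The returned trace records the global best after
#' initialisation (iteration 0) and after every update, and is monotone
#' non-decreasing by construction.
#'
#' @param objective A `poly_surface` or a vectorised function
#'   `f(x1, x2)`; must be finite everywhere inside the bounds.
#' @param config A [swarm_config()].
#' @param run_seed Integer seed for this run; defaults to `config$seed`.
#' @return A `pso_trace`: list with `trace` (data.frame
#'   `iteration, best_x1, best_x2, best_score`), `best_position`,
#'   `best_score`, `seed`.
#' @export
pso_maximize <- function(objective, config, run_seed = config$seed) {
  stopifnot(inherits(config, "swarm_config"))
  f <- .objective_fn(objective)
  b <- config$bounds
  n <- config$swarm_size
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(run_seed))
  rng <- b[, 2] - b[, 1]
  X <- cbind(stats::runif(n, b[1, 1], b[1, 2]),
             stats::runif(n, b[2, 1], b[2, 2]))
  V <- cbind(stats::runif(n, -config$v0_frac * rng[1], config$v0_frac * rng[1]),
             stats::runif(n, -config$v0_frac * rng[2], config$v0_frac * rng[2]))
  score <- f(X[, 1], X[, 2])
  .check_finite(score, X)
  P <- X; pscore <- score
  g <- which.max(pscore)
  gbest <- P[g, ]; gscore <- pscore[g]
  iters <- config$iterations
  trace <- data.frame(iteration = 0:iters, best_x1 = NA_real_,
                      best_x2 = NA_real_, best_score = NA_real_)
  trace[1, 2:4] <- c(gbest, gscore)
  vmax <- if (!is.null(config$velocity_clamp)) config$velocity_clamp * rng
  for (t in seq_len(iters) - 1L) {
    w <- inertia_at(t, config)
    r1 <- stats::runif(n); r2 <- stats::runif(n)
    V <- w * V + config$c1 * r1 * (P - X) +
         config$c2 * r2 * (matrix(gbest, n, 2, byrow = TRUE) - X)
    if (!is.null(vmax))
      V <- pmin(pmax(V, matrix(-vmax, n, 2, byrow = TRUE)),
                matrix(vmax, n, 2, byrow = TRUE))
    X <- X + V
    X[, 1] <- pmin(pmax(X[, 1], b[1, 1]), b[1, 2])
    X[, 2] <- pmin(pmax(X[, 2], b[2, 1]), b[2, 2])
    score <- f(X[, 1], X[, 2])
    .check_finite(score, X)
    imp <- score > pscore
    P[imp, ] <- X[imp, ]; pscore[imp] <- score[imp]
    g <- which.max(pscore)
    if (pscore[g] > gscore) { gbest <- P[g, ]; gscore <- pscore[g] }
    trace[t + 2L, 2:4] <- c(gbest, gscore)
  }
  structure(list(trace = trace, best_position = unname(gbest),
                 best_score = unname(gscore), seed = as.integer(run_seed)),
            class = "pso_trace")
}

.check_finite <- function(score, X) {
  bad <- which(!is.finite(score))
  if (length(bad))
    stop("non-finite objective value at position (", X[bad[1], 1], ", ",
         X[bad[1], 2], ")")
}

#' @export
print.pso_trace <- function(x, ...) {
  cat("<pso_trace> seed ", x$seed, ": best ", signif(x$best_score, 6),
      " at (", signif(x$best_position[1], 6), ", ",
      signif(x$best_position[2], 6), ") after ",
      nrow(x$trace) - 1L, " iterations\n", sep = "")
  invisible(x)
}

#' Multi-run particle swarm harness
#'
#' Performs `config$n_runs` independent swarm runs with per-run seeds
#' `config$seed + 0:(n_runs - 1)` and summarises the per-run best scores:
#' overall best (with its position and run index), mean and standard
#' deviation.  This mirrors the best/average/SD reporting convention of
#' multi-start stochastic optimisation studies.
#'
#' @inheritParams pso_maximize
#' @return A `pso_multirun`: list with `best_score`, `best_position`,
#'   `best_run`, `mean`, `sd` (0 with `single_run = TRUE` when
#'   `n_runs == 1`), `run_bests`, `traces` (list of `pso_trace`),
#'   `config`.
#' @export
multi_run <- function(objective, config) {
  stopifnot(inherits(config, "swarm_config"))
  traces <- lapply(seq_len(config$n_runs) - 1L, function(k)
    pso_maximize(objective, config, run_seed = config$seed + k))
  bests <- vapply(traces, `[[`, numeric(1), "best_score")
  i <- which.max(bests)
  structure(list(best_score = bests[i],
                 best_position = traces[[i]]$best_position,
                 best_run = i,
                 mean = mean(bests),
                 sd = if (length(bests) > 1L) stats::sd(bests) else 0,
                 single_run = length(bests) == 1L,
                 run_bests = bests,
                 traces = traces,
                 config = config),
            class = "pso_multirun")
}

#' @export
print.pso_multirun <- function(x, ...) {
  cat("<pso_multirun> ", length(x$run_bests), " runs: best ",
      signif(x$best_score, 6), " at (", signif(x$best_position[1], 6), ", ",
      signif(x$best_position[2], 6), "), mean ", signif(x$mean, 6), ", sd ",
      signif(x$sd, 4), "\n", sep = "")
  invisible(x)
}

#' Export a convergence trace as CSV
#'
#' Writes the per-iteration global-best history
#' (`iteration,best_x1,best_x2,best_score`), the data behind a convergence
#' plot.
#'
#' @param trace A `pso_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pso_trace"))
  utils::write.csv(trace$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a surface on a regular grid for contour overlays
#'
#' @param surface A `poly_surface`.
#' @param bounds Rectangle (see [swarm_config()]).
#' @param n Grid points per axis.
#' @return data.frame `x1, x2, predicted` with `n^2` rows.
#' @export
contour_grid <- function(surface, bounds = reproduction_bounds(), n = 51) {
  b <- .as_bounds(bounds)
  g1 <- seq(b[1, 1], b[1, 2], length.out = n)
  g2 <- seq(b[2, 1], b[2, 2], length.out = n)
  grid <- expand.grid(x1 = g1, x2 = g2)
  grid$predicted <- evaluate_surface(surface, grid$x1, grid$x2)
  grid
}
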