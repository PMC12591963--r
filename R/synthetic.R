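#' Specify a synthetic hedonic-panel generating process
#'
#' Describes the world the analysis pipeline assumes: a known quadratic
#' truth surface over the design region, scored by a panel of independent
#' assessors on the 9-point hedonic scale with additive Gaussian noise.
#' Defaults emulate the published study's structure: 50 panelists (the
#' study's panel size) and a per-panelist noise SD of 1.0 hedonic units, a
#' typical between-assessor spread for semi-trained panels, which puts the
#' run-mean standard error (`1/sqrt(50)` = 0.14) on the same order as the
#' published per-run SDs.
#'
#' @param surface Generating `poly_surface` (the truth).
#' @param noise_sd Per-panelist score SD, >= 0.
#' @param n_panelists Panelists per run, >= 1.
#' @param hedonic_clip Clip scores to \[1, 9\] (default `TRUE`).  Clipping,
#'   not rounding: published tables report continuous panel means.
#' @param round_scores Additionally round scores to whole hedonic points
#'   to emulate discrete ballots (default `FALSE`).
#' @param seed Integer seed.
#' @return A `truth_spec`.
#' @export
truth_spec <- function(surface, noise_sd = 1.0, n_panelists = 50L,
                       hedonic_clip = TRUE, round_scores = FALSE,
                       seed = 1L) {
  stopifnot(inherits(surface, "poly_surface"), noise_sd >= 0,
            n_panelists >= 1)
  structure(list(surface = surface, noise_sd = noise_sd,
                 n_panelists = as.integer(n_panelists),
                 hedonic_clip = isTRUE(hedonic_clip),
                 round_scores = isTRUE(round_scores),
                 seed = as.integer(seed)),
            class = "truth_spec")
}

#' Simulate a sensory panel over a design
#'
#' For every design run `i` and panelist `j`, draws
#' `score_ij = truth(x_i) + e_ij` with `e_ij ~ N(0, noise_sd^2)`,
#' optionally clipped to the hedonic range, and summarises per run as mean
#' and SD — the layout of a published response table.  A warning is raised
#' when clipping moves more than half of all scores, which signals that the
#' truth surface and the hedonic scale are mismatched.
#'
#' @param truth A [truth_spec()].
#' @param design A `ccd_design`.
#' @return A `panel_sim`: list with `summary` (data.frame
#'   `run, x1, x2, mean, sd`) and `raw` (long data.frame
#'   `run, panelist, score`).
#' @export
simulate_panel <- function(truth, design) {
  stopifnot(inherits(truth, "truth_spec"))
  xy <- .design_xy(design)
  n_runs <- nrow(xy)
  np <- truth$n_panelists
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(truth$seed)
  mu <- evaluate_surface(truth$surface, xy$x1, xy$x2)
  scores <- rep(mu, each = np) +
    stats::rnorm(n_runs * np, sd = truth$noise_sd)
  if (truth$round_scores) scores <- round(scores)
  if (truth$hedonic_clip) {
    clipped <- scores < 1 | scores > 9
    if (mean(clipped) > 0.5)
      warning("hedonic clipping moved ", round(100 * mean(clipped)),
              "% of scores: truth surface and 9-point scale are mismatched")
    scores <- pmin(pmax(scores, 1), 9)
  }
  raw <- data.frame(run = rep(seq_len(n_runs), each = np),
                    panelist = rep(seq_len(np), times = n_runs),
                    score = scores)
  means <- tapply(raw$score, raw$run, mean)
  sds <- if (np > 1L) tapply(raw$score, raw$run, stats::sd) else
    rep(0, n_runs)
  summary <- data.frame(run = seq_len(n_runs), x1 = xy$x1, x2 = xy$x2,
                        mean = as.numeric(means), sd = as.numeric(sds))
  structure(list(summary = summary, raw = raw, truth = truth),
            class = "panel_sim")
}

#' Parameter-recovery simulation experiment
#'
#' Repeats simulate -> fit -> optimise `n_replicates` times and reports,
#' per canonical coefficient, the bias and RMSE of the refitted
#' coefficients around the generating truth, together with the distance
#' between the recovered and true constrained optima.
#'
#' @param truth A [truth_spec()]; replicate `k` uses seed
#'   `truth$seed + k - 1`.
#' @param design A `ccd_design`.
#' @param n_replicates Number of simulation replicates (>= 1).
#' @param bounds Rectangle for the optimum-recovery comparison; defaults
#'   to the hull of the design's natural levels.
#' @return A `recovery_report`: list with `bias`, `rmse` (named numeric,
#'   b0..b12), `coefficients` (replicate x coefficient matrix),
#'   `argmax_truth`, `argmax_error` (per-replicate Euclidean distance in
#'   natural units) and `mean_argmax_error`.
#' @export
recovery_experiment <- function(truth, design, n_replicates = 100,
                                bounds = NULL) {
  stopifnot(inherits(truth, "truth_spec"), n_replicates >= 1)
  xy <- .design_xy(design)
  if (is.null(bounds))
    bounds <- list(x1 = range(xy$x1), x2 = range(xy$x2))
  true_co <- coef(truth$surface)
  opt_true <- bounded_optimum(truth$surface, bounds,
                              grid_step = 0.5, refine_step = 0.01)
  co_mat <- matrix(NA_real_, n_replicates, 6L,
                   dimnames = list(NULL, .canon_names))
  argmax_err <- numeric(n_replicates)
  for (k in seq_len(n_replicates)) {
    tk <- truth
    tk$seed <- truth$seed + k - 1L
    sim <- simulate_panel(tk, design)
    fit <- fit_quadratic(design, sim$summary$mean)
    co_mat[k, ] <- coef(fit$surface)
    opt_k <- bounded_optimum(fit$surface, bounds,
                             grid_step = 0.5, refine_step = 0.01)
    argmax_err[k] <- sqrt((opt_k$x1 - opt_true$x1)^2 +
                          (opt_k$x2 - opt_true$x2)^2)
  }
  err <- sweep(co_mat, 2L, true_co)
  structure(list(bias = colMeans(err),
                 rmse = sqrt(colMeans(err^2)),
                 coefficients = co_mat,
                 argmax_truth = c(x1 = opt_true$x1, x2 = opt_true$x2),
                 argmax_error = argmax_err,
                 mean_argmax_error = mean(argmax_err),
                 n_replicates = n_replicates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$n_replicates, " replicates\n", sep = "")
  cat("  coefficient bias: ", paste(names(x$bias), signif(x$bias, 3),
                                    sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  coefficient RMSE: ", paste(names(x$rmse), signif(x$rmse, 3),
                                    sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  mean argmax error: ", signif(x$mean_argmax_error, 4),
      " natural units\n", sep = "")
  invisible(x)
}

#' Write a simulated panel to CSV files
#'
#' Writes the per-run summary in the response-table layout
#' (`run,x1,x2,response_mean,response_sd`) and, optionally, the raw
#' per-panelist scores (`run,panelist,score`).
#'
#' @param sim A `panel_sim`.
#' @param path Summary CSV path.
#' @param raw_path Optional raw-score CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(sim, path, raw_path = NULL) {
  stopifnot(inherits(sim, "panel_sim"))
  write_response_table(sim$summary, path)
  if (!is.null(raw_path))
    utils::write.csv(sim$raw, raw_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
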