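#' Workflow configuration for the validation pipeline
#'
#' Bundles the selections and knobs of the design -> fit -> optimise ->
#' validate chain.  Validation failures are collected and reported
#' together, not one at a time.
#'
#' @param varieties Character vector of varieties to process (subset of
#'   [registry_varieties()]); may be empty.
#' @param responses Character vector of responses (subset of
#'   [registry_responses()]).
#' @param bounds `"reproduction"` (default) or `"experimental"`, or an
#'   explicit rectangle `list(x1 = , x2 = )`.
#' @param registry `"printed"` (default) or `"merged"` registry form.
#' @param swarm Named list of [swarm_config()] overrides
#'   (e.g. `list(n_runs = 5)`).
#' @param seed Master seed for the swarm runs.
#' @param tolerance PSO-vs-oracle acceptance tolerance on the best score.
#' @param out_dir Optional directory for CSV/JSON report files.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(varieties = registry_varieties(),
                            responses = registry_responses(),
                            bounds = "reproduction",
                            registry = "printed",
                            swarm = list(), seed = 1L, tolerance = 0.02,
                            out_dir = NULL) {
  problems <- character()
  bad_v <- setdiff(varieties, registry_varieties())
  if (length(bad_v))
    problems <- c(problems, paste0("unknown variety: ",
                                   paste(bad_v, collapse = ", ")))
  bad_r <- setdiff(responses, registry_responses())
  if (length(bad_r))
    problems <- c(problems, paste0("unknown response: ",
                                   paste(bad_r, collapse = ", ")))
  if (is.character(bounds)) {
    if (!bounds %in% c("reproduction", "experimental"))
      problems <- c(problems,
                    "bounds must be 'reproduction', 'experimental' or a rectangle")
  } else {
    ok <- tryCatch({ .as_bounds(bounds); TRUE }, error = function(e) FALSE)
    if (!ok) problems <- c(problems, "invalid bounds rectangle")
  }
  if (!registry %in% c("printed", "merged"))
    problems <- c(problems, "registry must be 'printed' or 'merged'")
  if (!is.numeric(tolerance) || tolerance <= 0)
    problems <- c(problems, "tolerance must be a positive number")
  bad_s <- setdiff(names(swarm),
                   setdiff(names(formals(swarm_config)), "bounds"))
  if (length(bad_s))
    problems <- c(problems, paste0("unknown swarm_config field: ",
                                   paste(bad_s, collapse = ", ")))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    problems <- c(problems, paste0("out_dir does not exist: ", out_dir))
  if (length(problems))
    stop("invalid workflow configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  rect <- if (is.character(bounds)) {
    if (bounds == "reproduction") reproduction_bounds() else
      experimental_bounds()
  } else bounds
  structure(list(varieties = varieties, responses = responses,
                 bounds = .as_bounds(rect), bounds_name =
                   if (is.character(bounds)) bounds else "custom",
                 registry = registry, swarm = swarm,
                 seed = as.integer(seed), tolerance = tolerance,
                 out_dir = out_dir),
            class = "workflow_config")
}

.config_swarm <- function(config) {
  args <- config$swarm
  args$bounds <- config$bounds
  if (is.null(args$seed)) args$seed <- config$seed
  do.call(swarm_config, args)
}

#' Validate registry surfaces: PSO versus grid-search oracle
#'
#' For each selected (variety, response) pair, loads the published
#' surface, runs the multi-run particle swarm, runs the exhaustive
#' grid-search oracle over the same rectangle, and emits one report row
#' in the published optimum-table format (optimal X1, X2, best score,
#' multi-run mean and SD) plus the oracle value and the deviation
#' `oracle - best`.  A pair passes when the deviation is at most
#' `config$tolerance`.
#'
#' @param config A [workflow_config()].
#' @return A `validation_report` data.frame (one row per pair) with
#'   attributes `passed` (logical scalar) and `config`.  An empty
#'   selection yields an empty, passing report.  When `config$out_dir` is
#'   set, `validation.csv` and `validation.json` are written there.
#' @export
run_validation <- function(config = workflow_config()) {
  stopifnot(inherits(config, "workflow_config"))
  sc <- .config_swarm(config)
  rows <- list()
  for (v in config$varieties) {
    for (r in config$responses) {
      surface <- printed_model(v, r, form = config$registry)
      mr <- multi_run(surface, sc)
      oracle <- bounded_optimum(surface, config$bounds)
      dev <- oracle$value - mr$best_score
      rows[[paste(v, r)]] <- data.frame(
        variety = v, response = r,
        x1 = mr$best_position[1], x2 = mr$best_position[2],
        best = mr$best_score, mean = mr$mean, sd = mr$sd,
        oracle_x1 = oracle$x1, oracle_x2 = oracle$x2,
        oracle = oracle$value, deviation = dev,
        pass = abs(dev) <= config$tolerance
      )
    }
  }
  report <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(variety = character(), response = character(),
                            x1 = numeric(), x2 = numeric(), best = numeric(),
                            mean = numeric(), sd = numeric(),
                            oracle_x1 = numeric(), oracle_x2 = numeric(),
                            oracle = numeric(), deviation = numeric(),
                            pass = logical())
  attr(report, "passed") <- all(report$pass)
  attr(report, "config") <- config
  class(report) <- c("validation_report", "data.frame")
  if (!is.null(config$out_dir)) {
    utils::write.csv(report, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(passed = all(report$pass),
                              bounds = config$bounds_name,
                              seed = config$seed,
                              tolerance = config$tolerance,
                              rows = as.data.frame(report)),
                         file.path(config$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x), " surface(s), ",
      if (isTRUE(attr(x, "passed"))) "all PASS" else "FAILURES present",
      "\n", sep = "")
  if (nrow(x))
    print(as.data.frame(x), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Refit a response table and compare against the published model
#'
#' Fits the full quadratic to a response table (a data.frame or a CSV in
#' the `run,x1,x2,response_mean,response_sd` layout), reports R-squared
#' and the per-run predicted column, and — when the table corresponds to
#' a registry pair — sets the refitted coefficients side by side with the
#' published equation and adds the registry-surface predictions.  When an
#' optimum validation row is supplied the percent difference between
#' prediction and experiment is computed for both conventions.
#'
#' @param table data.frame or CSV path.
#' @param variety,response Optional registry pair for the side-by-side
#'   comparison.
#' @param optimum Optional list/row with `x1`, `x2` and
#'   `experimental_mean` for the percent-difference check.
#' @return A `refit_report`: list with `fit` (an [fit_quadratic()] result
#'   with ANOVA populated), `predictions` (data.frame
#'   `run, x1, x2, mean, refit_predicted[, registry_predicted]`),
#'   `coefficients` (refit vs printed, when a registry pair is given) and
#'   `pct_difference` (when `optimum` is given).
#' @export
run_refit <- function(table, variety = NULL, response = NULL,
                      optimum = NULL) {
  if (is.character(table)) table <- read_response_table(table)
  stopifnot(all(c("x1", "x2", "mean") %in% names(table)))
  fit <- anova_decompose(fit_quadratic(table, table$mean,
                                       label = paste(variety, response)))
  preds <- data.frame(run = if ("run" %in% names(table)) table$run else
                        seq_len(nrow(table)),
                      x1 = table$x1, x2 = table$x2, mean = table$mean,
                      refit_predicted = fit$fitted)
  coef_cmp <- NULL
  if (!is.null(variety) && !is.null(response)) {
    printed <- printed_model(variety, response)
    preds$registry_predicted <- evaluate_surface(printed, table$x1, table$x2)
    coef_cmp <- data.frame(coefficient = .canon_names,
                           refit = unname(coef(fit$surface)),
                           printed = unname(coef(printed)))
  }
  pct <- NULL
  if (!is.null(optimum)) {
    pred_opt <- evaluate_surface(fit$surface, optimum$x1, optimum$x2)
    pct <- data.frame(
      x1 = optimum$x1, x2 = optimum$x2, predicted = pred_opt,
      experimental = optimum$experimental_mean,
      pct_diff_experimental = percent_difference(
        pred_opt, optimum$experimental_mean, "experimental"),
      pct_diff_predicted = percent_difference(
        pred_opt, optimum$experimental_mean, "predicted"))
  }
  structure(list(fit = fit, predictions = preds, coefficients = coef_cmp,
                 pct_difference = pct),
            class = "refit_report")
}

#' @export
print.refit_report <- function(x, ...) {
  cat("<refit_report> R2 = ", sprintf("%.2f%%", x$fit$R2), "\n", sep = "")
  print(utils::head(x$predictions, 13), row.names = FALSE, digits = 4)
  if (!is.null(x$coefficients)) {
    cat("coefficients (refit vs printed):\n")
    print(x$coefficients, row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/cli/rsmpso` script:
#' `design`, `simulate`, `fit`, `optimize`, `validate`, `report`.
#' Global flags: `--seed <int>`, `--bounds {reproduction,experimental}`,
#' `--registry {printed,merged}`, `--out <dir>`; subcommand flags:
#' `--variety`, `--response`, `--table <csv>`, `--noise-sd`,
#' `--panelists`, `--runs`, `--tolerance`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return Exit status, invisibly: 0 on success, 1 on a validation
#'   failure or usage error.
#' @export
rsmpso_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rsmpso <design|simulate|fit|optimize|validate|report> [flags]",
    "  global: --seed <int> --bounds <reproduction|experimental>",
    "          --registry <printed|merged> --out <dir>",
    "  fit/simulate: --variety <v> --response <r> --table <csv>",
    "  simulate: --noise-sd <x> --panelists <n>",
    "  optimize/validate: --runs <n> --tolerance <x>", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1]]
  opts <- .parse_flags(args[-1])
  seed <- as.integer(opts[["seed"]] %||% 1L)
  bounds <- opts[["bounds"]] %||% "reproduction"
  registry <- opts[["registry"]] %||% "printed"
  out <- opts[["out"]]
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  status <- 0L
  switch(cmd,
    design = {
      d <- pilaf_design()
      if (!is.null(out)) write_design(d, file.path(out, "design.csv"))
      print(d)
    },
    simulate = {
      surface <- printed_model(opts[["variety"]] %||% "firik",
                               opts[["response"]] %||% "taste",
                               form = "merged")
      truth <- truth_spec(surface,
                          noise_sd = as.numeric(opts[["noise-sd"]] %||% 1),
                          n_panelists =
                            as.integer(opts[["panelists"]] %||% 50),
                          seed = seed)
      sim <- simulate_panel(truth, pilaf_design())
      if (!is.null(out))
        write_panel(sim, file.path(out, "panel.csv"),
                    file.path(out, "panel_raw.csv"))
      print(utils::head(sim$summary, 13))
    },
    fit = {
      tab <- if (!is.null(opts[["table"]])) opts[["table"]] else
        sensory_table(opts[["variety"]] %||% "karakilcik",
                      opts[["response"]] %||% "taste")
      rep <- run_refit(tab, variety = opts[["variety"]],
                       response = opts[["response"]])
      if (!is.null(out))
        utils::write.csv(rep$predictions, file.path(out, "refit.csv"),
                         row.names = FALSE, quote = FALSE)
      print(rep)
    },
    optimize = {
      surface <- printed_model(opts[["variety"]] %||% "firik",
                               opts[["response"]] %||% "taste",
                               form = registry)
      cfg <- workflow_config(bounds = bounds, registry = registry,
                             seed = seed,
                             swarm = list(n_runs =
                               as.integer(opts[["runs"]] %||% 30)))
      mr <- multi_run(surface, .config_swarm(cfg))
      if (!is.null(out))
        write_trace(mr$traces[[mr$best_run]],
                    file.path(out, "best_trace.csv"))
      print(mr)
    },
    validate = ,
    report = {
      cfg <- workflow_config(
        varieties = if (!is.null(opts[["variety"]])) opts[["variety"]] else
          registry_varieties(),
        responses = if (!is.null(opts[["response"]])) opts[["response"]] else
          registry_responses(),
        bounds = bounds, registry = registry, seed = seed,
        tolerance = as.numeric(opts[["tolerance"]] %||% 0.02),
        swarm = list(n_runs = as.integer(opts[["runs"]] %||% 30)),
        out_dir = out)
      rep <- run_validation(cfg)
      print(rep)
      status <- if (isTRUE(attr(rep, "passed"))) 0L else 1L
    },
    {
      message("unknown subcommand: ", cmd, "\n", usage)
      status <- 1L
    }
  )
  invisible(status)
}

.parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[[i + 1L]], "--"))
      stop("flag --", key, " needs a value")
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}
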