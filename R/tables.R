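# Published sensory-panel summaries for the 13-run formulation design:
# per-run experimental mean +/- SD on the 9-point hedonic scale and the
# model-predicted value, for each variety x response, plus the published
# optimum-formulation validation row.  Rows follow the design run order of
# pilaf_design(); the five centre replicates carry identical printed means.

.sensory <- local({
  x1 <- c(140, 150, 140, 140, 135, 145, 145, 140, 140, 140, 135, 140, 130)
  x2 <- c(400, 400, 400, 400, 425, 425, 375, 350, 450, 400, 375, 400, 400)
  mk <- function(mean, sd, pred)
    data.frame(run = 1:13, x1 = x1, x2 = x2, mean = mean, sd = sd,
               predicted = pred)
  list(
    siyez = list(
      taste = mk(
        c(7.15, 6.99, 7.15, 7.15, 6.65, 7.56, 6.52, 6.28, 6.60, 7.15, 6.82, 7.15, 6.37),
        c(0.07, 0.11, 0.20, 0.04, 0.08, 0.13, 0.20, 0.11, 0.07, 0.27, 0.11, 0.16, 0.08),
        c(7.25, 7.10, 7.25, 7.25, 6.63, 7.54, 6.68, 6.29, 6.80, 7.25, 6.98, 7.25, 6.47)),
      color = mk(
        c(6.67, 7.51, 6.67, 6.67, 7.17, 7.00, 6.94, 6.43, 6.97, 6.67, 6.31, 6.67, 6.99),
        c(0.72, 0.61, 0.61, 0.74, 0.08, 0.52, 0.23, 0.20, 0.25, 0.14, 0.61, 0.34, 0.27),
        c(6.65, 7.49, 6.65, 6.65, 7.04, 6.90, 6.97, 6.36, 7.01, 6.65, 6.32, 6.65, 6.98)),
      smell = mk(
        c(5.40, 7.33, 5.40, 5.40, 5.50, 6.34, 6.70, 6.80, 6.36, 5.40, 5.10, 5.40, 5.23),
        c(0.38, 0.06, 0.21, 0.27, 0.14, 0.16, 0.07, 0.62, 0.28, 0.54, 0.31, 0.20, 0.18),
        c(5.46, 7.45, 5.46, 5.46, 5.54, 6.27, 6.79, 6.78, 6.51, 5.46, 5.30, 5.46, 5.23)),
      general_acceptance = mk(
        c(6.79, 6.64, 6.79, 6.79, 6.32, 7.18, 6.19, 5.97, 6.27, 6.79, 6.48, 6.79, 6.05),
        c(0.06, 0.89, 0.30, 0.47, 0.93, 0.07, 0.79, 0.55, 0.75, 0.13, 0.18, 0.13, 1.27),
        c(6.80, 6.65, 6.80, 6.80, 6.21, 7.08, 6.26, 5.89, 6.37, 6.80, 6.54, 6.80, 6.06))
    ),
    firik = list(
      taste = mk(
        c(7.51, 6.53, 7.51, 7.51, 6.74, 7.15, 7.01, 6.84, 6.60, 7.51, 7.16, 7.51, 6.53),
        c(0.45, 0.07, 0.14, 0.18, 0.21, 0.16, 0.24, 0.40, 0.07, 0.22, 0.31, 0.25, 0.20),
        c(7.51, 6.57, 7.51, 7.51, 6.85, 7.17, 7.00, 6.83, 6.61, 7.51, 7.24, 7.51, 6.49)),
      color = mk(
        c(6.84, 7.42, 6.84, 6.84, 6.96, 7.20, 6.33, 5.80, 7.04, 6.84, 6.63, 6.84, 7.54),
        c(0.23, 0.19, 0.37, 0.49, 0.25, 0.06, 0.46, 0.21, 0.14, 0.38, 0.16, 0.30, 0.37),
        c(6.78, 7.36, 6.78, 6.78, 7.03, 7.24, 6.36, 5.74, 6.96, 6.78, 6.68, 6.78, 7.46)),
      smell = mk(
        c(5.67, 7.68, 5.67, 5.67, 5.43, 7.54, 5.98, 6.07, 7.81, 5.67, 5.36, 5.67, 5.40),
        c(0.10, 0.56, 0.17, 0.11, 0.24, 0.14, 0.58, 0.10, 0.07, 0.16, 0.05, 0.18, 0.06),
        c(5.59, 7.67, 5.59, 5.59, 5.57, 7.52, 5.94, 6.00, 7.70, 5.59, 5.46, 5.59, 5.24)),
      general_acceptance = mk(
        c(6.07, 6.29, 6.07, 6.07, 5.53, 7.46, 4.80, 6.11, 7.51, 6.07, 6.78, 6.07, 6.22),
        c(0.13, 0.03, 0.17, 0.15, 0.35, 0.19, 0.34, 0.10, 0.41, 0.58, 0.12, 0.29, 0.09),
        c(6.01, 6.19, 6.01, 6.01, 5.60, 7.57, 4.91, 6.03, 7.45, 6.01, 6.85, 6.01, 6.17))
    ),
    karakilcik = list(
      taste = mk(
        c(6.53, 5.68, 6.53, 6.53, 6.43, 6.76, 5.83, 5.85, 7.05, 6.53, 6.23, 6.53, 5.82),
        c(0.07, 0.16, 0.25, 0.27, 0.10, 0.15, 0.04, 0.24, 0.35, 0.04, 0.31, 0.10, 0.19),
        c(6.61, 5.77, 6.61, 6.61, 6.54, 6.85, 5.88, 5.92, 7.13, 6.61, 6.30, 6.61, 5.88)),
      color = mk(
        c(7.25, 6.73, 7.25, 7.25, 6.84, 7.48, 6.60, 5.97, 7.47, 7.25, 6.25, 7.25, 5.88),
        c(0.10, 0.49, 0.21, 0.08, 0.18, 0.20, 0.14, 0.16, 0.07, 0.16, 0.69, 0.28, 0.06),
        c(7.12, 6.62, 7.12, 7.12, 6.83, 7.42, 6.54, 5.85, 7.32, 7.12, 6.24, 7.12, 5.73)),
      smell = mk(
        c(6.72, 6.69, 6.72, 6.72, 6.16, 7.58, 5.85, 5.85, 7.23, 6.72, 6.60, 6.72, 5.92),
        c(0.03, 0.11, 0.31, 0.23, 0.79, 0.11, 0.05, 0.73, 0.95, 0.08, 0.17, 0.14, 0.21),
        c(6.75, 6.70, 6.75, 6.75, 6.22, 7.67, 5.90, 5.88, 7.26, 6.75, 6.62, 6.75, 5.97)),
      general_acceptance = mk(
        c(7.15, 6.25, 7.15, 7.15, 6.73, 7.44, 6.37, 6.02, 7.75, 7.15, 6.06, 7.15, 5.21),
        c(0.57, 0.03, 0.21, 0.27, 0.35, 0.44, 0.54, 0.20, 0.07, 0.18, 0.41, 0.35, 0.48),
        c(7.09, 6.17, 7.09, 7.09, 6.74, 7.45, 6.39, 5.95, 7.68, 7.09, 6.07, 7.09, 5.15))
    )
  )
})

# Published optimum-formulation validation rows: model prediction at the
# recommended (X1, X2), experimental re-measurement, and published percent
# difference.
.sensory_optimum <- local({
  mk <- function(x1, x2, pred, exp_mean, exp_sd, pct)
    data.frame(response = registry_responses(), x1 = x1, x2 = x2,
               predicted = pred, experimental_mean = exp_mean,
               experimental_sd = exp_sd, pct_difference = pct)
  list(
    siyez = mk(150, 450, c(7.75, 7.08, 7.67, 7.37),
               c(7.50, 7.19, 7.83, 7.75), c(0.31, 0.06, 0.38, 0.27),
               c(3.22, 1.52, 2.04, 4.90)),
    firik = mk(147, 435, c(6.68, 7.52, 8.70, 8.75),
               c(7.12, 7.08, 8.46, 8.49), c(0.23, 0.21, 0.41, 0.14),
               c(6.17, 5.85, 2.75, 2.97)),
    karakilcik = mk(146, 450, c(7.16, 7.54, 8.58, 7.76),
                    c(7.23, 7.68, 8.45, 7.92), c(0.07, 0.07, 0.42, 0.10),
                    c(0.96, 1.82, 1.51, 2.02))
  )
})

#' Published per-run sensory means for one variety and response
#'
#' The 13-run hedonic-panel summary (experimental mean, SD and published
#' model prediction) aligned with [pilaf_design()] run order.
#'
#' @param variety `"siyez"`, `"firik"` or `"karakilcik"`.
#' @param response `"taste"`, `"color"`, `"smell"` or
#'   `"general_acceptance"`.
#' @return data.frame `run, x1, x2, mean, sd, predicted`.
#' @export
sensory_table <- function(variety, response) {
  variety <- match.arg(variety, registry_varieties())
  response <- match.arg(response, registry_responses())
  .sensory[[variety]][[response]]
}

#' Published optimum-formulation validation row for one variety
#'
#' Model predictions at the recommended formulation, the experimental
#' re-measurement, and the published percent difference.
#'
#' @inheritParams sensory_table
#' @return data.frame with one row per response.
#' @export
sensory_optimum <- function(variety) {
  variety <- match.arg(variety, registry_varieties())
  .sensory_optimum[[variety]]
}

#' Read / write response tables in the delimited layout
#'
#' Response tables travel as CSV `run,x1,x2,response_mean,response_sd`
#' (extra columns preserved).
#'
#' @param table data.frame with at least `run, x1, x2, mean, sd`.
#' @param path CSV path.
#' @return `write_response_table()` returns `path` invisibly;
#'   `read_response_table()` a data.frame with canonical column names.
#' @export
write_response_table <- function(table, path) {
  stopifnot(all(c("run", "x1", "x2", "mean", "sd") %in% names(table)))
  out <- table
  names(out)[names(out) == "mean"] <- "response_mean"
  names(out)[names(out) == "sd"] <- "response_sd"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  tab <- utils::read.csv(path)
  names(tab)[names(tab) == "response_mean"] <- "mean"
  names(tab)[names(tab) == "response_sd"] <- "sd"
  need <- c("run", "x1", "x2", "mean")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("response table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), " (found: ",
         paste(names(tab), collapse = ", "), ")")
  bad <- which(!is.finite(tab$mean))
  if (length(bad))
    stop("non-numeric response_mean in row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  tab
}
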