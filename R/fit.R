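#' Fit a full second-order response surface by ordinary least squares
#'
#' Fits \eqn{y = b_0 + b_1 X_1 + b_2 X_2 + b_{11} X_1^2 + b_{22} X_2^2 +
#' b_{12} X_1 X_2} in natural units to per-run responses.  Replicated rows
#' (centre points) enter as printed, so replication weights the fit at the
#' centre exactly as the published analyses did.
#'
#' @param design A `ccd_design`, or a data.frame with columns `x1` and `x2`
#'   (natural units).
#' @param responses Numeric vector of per-run responses aligned with the
#'   design rows.
#' @param label Label stored on the fitted surface.
#' @return An `rsm_fit`: list with `surface` (a `poly_surface`, provenance
#'   `"fitted"`), `R2` and `adj_R2` (percent), `fitted`, `residuals`,
#'   `sigma`, and the model frame `data`.
#' @examples
#' d <- pilaf_design()
#' fit <- fit_quadratic(d, sensory_table("karakilcik", "taste")$mean)
#' round(fit$R2, 2)
#' @export
fit_quadratic <- function(design, responses, label = "fitted surface") {
  xy <- .design_xy(design)
  y <- as.numeric(responses)
  if (length(y) != nrow(xy))
    stop("length(responses) [", length(y), "] does not match the design [",
         nrow(xy), " rows]")
  if (nrow(unique(xy)) < 6L)
    stop("need at least 6 distinct design points to fit 6 coefficients; got ",
         nrow(unique(xy)))
  df <- data.frame(y = y, x1 = xy$x1, x2 = xy$x2)
  fit <- stats::lm(y ~ x1 + x2 + I(x1^2) + I(x2^2) + I(x1 * x2), data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    mono <- c("(Intercept)" = "b0", x1 = "X1", x2 = "X2", `I(x1^2)` = "X1^2",
              `I(x2^2)` = "X2^2", `I(x1 * x2)` = "X1*X2")
    stop("rank-deficient design matrix; aliased monomial(s): ",
         paste(mono[names(co)[is.na(co)]], collapse = ", "))
  }
  # interpolating noiseless data is a supported path; silence summary.lm's
  # "essentially perfect fit" advisory
  sm <- suppressWarnings(summary(fit))
  surface <- poly_surface(unname(co[c("(Intercept)", "x1", "x2", "I(x1^2)",
                                      "I(x2^2)", "I(x1 * x2)")]),
                          label = label, provenance = "fitted")
  structure(list(surface = surface,
                 R2 = 100 * sm$r.squared,
                 adj_R2 = 100 * sm$adj.r.squared,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 sigma = sm$sigma,
                 data = df,
                 lm = fit,
                 anova = NULL),
            class = "rsm_fit")
}

.design_xy <- function(design) {
  if (inherits(design, "ccd_design"))
    return(data.frame(x1 = design$design$x1_natural,
                      x2 = design$design$x2_natural))
  if (is.data.frame(design) && all(c("x1", "x2") %in% names(design)))
    return(data.frame(x1 = as.numeric(design$x1), x2 = as.numeric(design$x2)))
  stop("`design` must be a ccd_design or a data.frame with columns x1, x2")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("<rsm_fit> R2 = ", sprintf("%.2f%%", x$R2), ", adjusted R2 = ",
      sprintf("%.2f%%", x$adj_R2), ", sigma = ", signif(x$sigma, 4), "\n",
      sep = "")
  print(x$surface)
  if (!is.null(x$anova)) {
    cat("ANOVA (adjusted SS):\n")
    print(x$anova, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
predict.rsm_fit <- function(object, x1, x2, ...) {
  evaluate_surface(object$surface, x1, x2)
}

#' ANOVA decomposition with lack-of-fit / pure-error split
#'
#' Partitions the model sum of squares into per-monomial sources using
#' adjusted (partial, drop-one) sums of squares, and splits the residual
#' into lack of fit and pure error using replicated design points.  Pure
#' error is the within-replicate-group variation; when replicate responses
#' are identical (as in published tables of panel means) the pure-error SS
#' is zero and the lack-of-fit F is flagged undefined rather than
#' fabricated.
#'
#' @param fit An `rsm_fit` from [fit_quadratic()].
#' @return The fit with `$anova` populated: one row per source (`X1`,
#'   `X2`, `X1^2`, `X2^2`, `X1*X2`, `lack_of_fit`, `pure_error`,
#'   `residual`, `total`) with columns `df`, `SS`, `MS`, `F`, `p`, plus
#'   attribute `lack_of_fit_defined`.
#' @export
anova_decompose <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  df <- fit$data
  n <- nrow(df)
  full <- fit$lm
  sse <- sum(stats::residuals(full)^2)
  p <- length(stats::coef(full))
  X <- stats::model.matrix(full)
  terms_drop <- c(X1 = "x1", X2 = "x2", `X1^2` = "I(x1^2)",
                  `X2^2` = "I(x2^2)", `X1*X2` = "I(x1 * x2)")
  adj <- vapply(terms_drop, function(tm) {
    reduced <- stats::lm.fit(X[, colnames(X) != tm, drop = FALSE], df$y)
    sum(reduced$residuals^2) - sse
  }, numeric(1))
  # replicate groups for pure error
  key <- paste(df$x1, df$x2)
  groups <- split(df$y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- n - length(groups)
  df_res <- n - p
  df_lof <- df_res - df_pe
  ss_lof <- sse - ss_pe
  mse <- sse / df_res
  lof_defined <- ss_pe > 1e-12 && df_pe > 0 && df_lof > 0
  src_F <- (adj / 1) / mse
  src_p <- stats::pf(src_F, 1, df_res, lower.tail = FALSE)
  lof_F <- if (lof_defined) (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
  lof_p <- if (lof_defined)
    stats::pf(lof_F, df_lof, df_pe, lower.tail = FALSE) else NA_real_
  sst <- sum((df$y - mean(df$y))^2)
  tab <- data.frame(
    source = c(names(terms_drop), "lack_of_fit", "pure_error", "residual",
               "total"),
    df = c(rep(1L, 5L), df_lof, df_pe, df_res, n - 1L),
    SS = c(adj, ss_lof, ss_pe, sse, sst),
    MS = c(adj, if (df_lof > 0) ss_lof / df_lof else NA_real_,
           if (df_pe > 0) ss_pe / df_pe else NA_real_, mse, NA_real_),
    F = c(src_F, lof_F, NA_real_, NA_real_, NA_real_),
    p = c(src_p, lof_p, NA_real_, NA_real_, NA_real_)
  )
  attr(tab, "lack_of_fit_defined") <- lof_defined
  fit$anova <- tab
  fit
}
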