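#' Second-order response surface as an explicit term list
#'
#' A quadratic polynomial in two natural-unit factors,
#' \deqn{y = b_0 + b_1 X_1 + b_2 X_2 + b_{11} X_1^2 + b_{22} X_2^2 + b_{12} X_1 X_2,}
#' stored as an ordered list of `(coefficient, p1, p2)` monomials with total
#' degree at most 2.  Duplicate monomials are permitted in storage — some
#' published equations print the same monomial twice — and evaluation sums
#' them; [merge_surface()] collapses the term list to the canonical
#' six-coefficient form.
#'
#' @param coef Either a numeric vector of the six canonical coefficients
#'   `c(b0, b1, b2, b11, b22, b12)` (names optional) or `NULL` when `terms`
#'   is given.
#' @param terms Optional data.frame with columns `coef`, `p1`, `p2` giving
#'   the monomial list explicitly (exponents in {0, 1, 2}, `p1 + p2 <= 2`).
#' @param label Text label carried through reports.
#' @param provenance One of `"printed"`, `"fitted"`, `"synthetic"`.
#' @return An object of class `poly_surface`.
#' @examples
#' s <- poly_surface(c(0, 0, 0, -1, -1, 0))   # -(X1^2 + X2^2)
#' evaluate_surface(s, 1, 2)                  # -5
#' stationary_point(s)$classification         # "maximum"
#' @export
poly_surface <- function(coef = NULL, terms = NULL, label = "",
                         provenance = c("synthetic", "printed", "fitted")) {
  provenance <- match.arg(provenance)
  if (is.null(terms)) {
    stopifnot(is.numeric(coef), length(coef) == 6L, all(is.finite(coef)))
    terms <- data.frame(coef = as.numeric(coef),
                        p1 = c(0, 1, 0, 2, 0, 1),
                        p2 = c(0, 0, 1, 0, 2, 1))
  } else {
    stopifnot(is.data.frame(terms), all(c("coef", "p1", "p2") %in% names(terms)))
    terms <- data.frame(coef = as.numeric(terms$coef),
                        p1 = as.integer(terms$p1), p2 = as.integer(terms$p2))
    if (any(terms$p1 < 0 | terms$p2 < 0 | terms$p1 + terms$p2 > 2))
      stop("term exponents must be non-negative with total degree <= 2")
    if (any(!is.finite(terms$coef))) stop("non-finite coefficient in terms")
  }
  structure(list(terms = terms, label = label, provenance = provenance),
            class = "poly_surface")
}

.canon_pow <- data.frame(p1 = c(0, 1, 0, 2, 0, 1), p2 = c(0, 0, 1, 0, 2, 1))
.canon_names <- c("b0", "b1", "b2", "b11", "b22", "b12")

#' Merge duplicate monomials into the canonical six-term form
#'
#' @param surface A `poly_surface`.
#' @return A `poly_surface` with exactly one term per canonical monomial
#'   (zero coefficients retained), in the order b0, b1, b2, b11, b22, b12.
#' @export
merge_surface <- function(surface) {
  stopifnot(inherits(surface, "poly_surface"))
  co <- coef(surface)
  poly_surface(co, label = surface$label, provenance = surface$provenance)
}

#' @export
coef.poly_surface <- function(object, ...) {
  tt <- object$terms
  out <- vapply(seq_len(6L), function(i) {
    sum(tt$coef[tt$p1 == .canon_pow$p1[i] & tt$p2 == .canon_pow$p2[i]])
  }, numeric(1))
  names(out) <- .canon_names
  out
}

#' @export
print.poly_surface <- function(x, digits = 6, ...) {
  co <- signif(coef(x), digits)
  mono <- c("", "*X1", "*X2", "*X1^2", "*X2^2", "*X1*X2")
  body <- paste0(ifelse(co >= 0 & seq_along(co) > 1, "+", ""), co, mono,
                 collapse = " ")
  cat("<poly_surface", if (nzchar(x$label)) paste0(" '", x$label, "'"),
      "> [", x$provenance, "]\n  y = ", body, "\n", sep = "")
  if (nrow(x$terms) != 6L)
    cat("  (stored as ", nrow(x$terms), " terms; duplicates summed above)\n",
        sep = "")
  invisible(x)
}

#' Evaluate a response surface
#'
#' Sums `coef * X1^p1 * X2^p2` over every stored term, duplicates included,
#' so the as-printed and merged representations of the same surface agree
#' exactly.
#'
#' @param surface A `poly_surface`.
#' @param x1,x2 Numeric vectors (recycled to a common length) of natural
#'   factor values.
#' @return Numeric vector of responses.
#' @export
evaluate_surface <- function(surface, x1, x2) {
  stopifnot(inherits(surface, "poly_surface"))
  n <- max(length(x1), length(x2))
  x1 <- rep_len(as.numeric(x1), n); x2 <- rep_len(as.numeric(x2), n)
  tt <- surface$terms
  out <- numeric(n)
  for (k in seq_len(nrow(tt)))
    out <- out + tt$coef[k] * x1^tt$p1[k] * x2^tt$p2[k]
  out
}

#' Stationary point of a quadratic surface
#'
#' Solves the 2x2 linear gradient system of the merged canonical form and
#' classifies the critical point from the Hessian
#' \eqn{H = [[2 b_{11}, b_{12}], [b_{12}, 2 b_{22}]]}: negative definite is
#' a maximum, positive definite a minimum, indefinite a saddle; a singular
#' gradient system is reported as degenerate (with `x1`/`x2` `NA`), not an
#' error.
#'
#' @param surface A `poly_surface`.
#' @return List with `x1`, `x2`, `value` and
#'   `classification` in `c("maximum", "minimum", "saddle", "degenerate")`.
#' @export
stationary_point <- function(surface) {
  co <- coef(surface)
  H <- matrix(c(2 * co["b11"], co["b12"], co["b12"], 2 * co["b22"]), 2, 2)
  detH <- H[1, 1] * H[2, 2] - H[1, 2] * H[2, 1]
  scale <- max(abs(H), abs(co[c("b1", "b2")]), 1)
  if (!is.finite(detH) || abs(detH) <= 1e-12 * scale^2) {
    return(list(x1 = NA_real_, x2 = NA_real_, value = NA_real_,
                classification = "degenerate"))
  }
  xy <- solve(H, -c(co["b1"], co["b2"]))
  cls <- if (detH > 0 && H[1, 1] < 0) "maximum"
         else if (detH > 0 && H[1, 1] > 0) "minimum"
         else "saddle"
  list(x1 = xy[1], x2 = xy[2],
       value = evaluate_surface(surface, xy[1], xy[2]),
       classification = cls)
}

.as_bounds <- function(bounds) {
  if (is.list(bounds) && all(c("x1", "x2") %in% names(bounds)))
    bounds <- rbind(bounds$x1, bounds$x2)
  bounds <- matrix(as.numeric(bounds), nrow = 2)
  if (any(!is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a non-empty rectangle: list(x1 = c(lo, hi), x2 = c(lo, hi))")
  dimnames(bounds) <- list(c("x1", "x2"), c("lo", "hi"))
  bounds
}

#' Maximise a surface over a rectangle by exhaustive grid search
#'
#' A deliberately simple, derivative-free oracle for the particle swarm
#' optimiser: an exhaustive coarse grid over the rectangle followed by one
#' refinement pass at `refine_step` resolution around the best coarse cell.
#' For a quadratic this brackets the constrained maximum to within the fine
#' grid resolution.
#'
#' @param surface A `poly_surface` (or any function of `(x1, x2)`).
#' @param bounds `list(x1 = c(lo, hi), x2 = c(lo, hi))` in natural units.
#' @param grid_step Coarse grid spacing (natural units), > 0.
#' @param refine_step Fine grid spacing of the refinement pass.
#' @return List with `x1`, `x2`, `value`.
#' @export
bounded_optimum <- function(surface, bounds, grid_step = 0.5,
                            refine_step = 0.001) {
  stopifnot(grid_step > 0, refine_step > 0)
  b <- .as_bounds(bounds)
  f <- if (inherits(surface, "poly_surface"))
         function(x1, x2) evaluate_surface(surface, x1, x2)
       else match.fun(surface)
  search <- function(lo1, hi1, lo2, hi2, step) {
    g1 <- seq(lo1, hi1, by = step)
    if (g1[length(g1)] < hi1) g1 <- c(g1, hi1)
    g2 <- seq(lo2, hi2, by = step)
    if (g2[length(g2)] < hi2) g2 <- c(g2, hi2)
    v <- outer(g1, g2, f)
    i <- arrayInd(which.max(v), dim(v))
    list(x1 = g1[i[1]], x2 = g2[i[2]], value = v[i])
  }
  coarse <- search(b[1, 1], b[1, 2], b[2, 1], b[2, 2], grid_step)
  fine <- search(max(b[1, 1], coarse$x1 - grid_step),
                 min(b[1, 2], coarse$x1 + grid_step),
                 max(b[2, 1], coarse$x2 - grid_step),
                 min(b[2, 2], coarse$x2 + grid_step), refine_step)
  if (fine$value >= coarse$value) fine else coarse
}

#' Percent difference between a model prediction and an experimental value
#'
#' `100 * |predicted - experimental| / denominator`, where the denominator
#' is the experimental value by default.  Published validation tables are
#' not always explicit about the convention; the predicted-value denominator
#' is available via `denominator = "predicted"`.
#'
#' @param predicted,experimental Numeric vectors.
#' @param denominator `"experimental"` (default) or `"predicted"`.
#' @return Numeric vector of percent differences.
#' @export
percent_difference <- function(predicted, experimental,
                               denominator = c("experimental", "predicted")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "experimental") experimental else predicted
  if (any(den == 0)) stop("percent difference undefined: zero denominator")
  100 * abs(predicted - experimental) / abs(den)
}

#' Serialize / load a surface as a JSON term list
#'
#' @param surface A `poly_surface`.
#' @param path JSON file path.
#' @return `write_surface()` returns `path` invisibly; `read_surface()` a
#'   `poly_surface`.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "poly_surface"))
  jsonlite::write_json(list(label = surface$label,
                            provenance = surface$provenance,
                            terms = surface$terms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly_surface(terms = as.data.frame(x$terms), label = x$label %||% "",
               provenance = x$provenance %||% "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
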