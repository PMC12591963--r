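#' CIELAB color point
#'
#' @param L Lightness.
#' @param a Green(-)/red(+) axis.
#' @param b Blue(-)/yellow(+) axis.
#' @return A `color_point`.
#' @export
color_point <- function(L, a, b) {
  stopifnot(is.finite(L), is.finite(a), is.finite(b))
  structure(list(L = L, a = a, b = b), class = "color_point")
}

.ab <- function(color, a, b) {
  if (inherits(color, "color_point")) c(color$a, color$b) else c(color, a)
}

#' DPPH radical scavenging activity
#'
#' Percent inhibition from control and sample absorbances at 517 nm:
#' `(A0 - A1) / A0 * 100`.
#'
#' @param a0 Control absorbance (> 0).
#' @param a1 Sample absorbance (>= 0).
#' @return Percent inhibition.
#' @examples
#' dpph_inhibition(0.8, 0.2)  # 75
#' @export
dpph_inhibition <- function(a0, a1) {
  if (any(a0 <= 0)) stop("control absorbance A0 must be > 0")
  if (any(a1 < 0)) stop("sample absorbance A1 must be >= 0")
  (a0 - a1) / a0 * 100
}

#' Chroma (color intensity)
#'
#' `C = sqrt(a^2 + b^2)`, the radial coordinate of the CIELAB a-b plane.
#'
#' @param color A [color_point()], or the `a` value when `b` is supplied.
#' @param a,b Numeric scalars, used when `color` is numeric.
#' @return Chroma.
#' @examples
#' chroma(color_point(15.15, 1.67, 3.06))  # 3.49
#' @export
chroma <- function(color, a = NULL, b = NULL) {
  ab <- if (inherits(color, "color_point")) c(color$a, color$b) else c(color, a)
  sqrt(ab[1]^2 + ab[2]^2)
}

#' Hue angle in degrees
#'
#' Quadrant-correct two-argument arctangent of `(b, a)` mapped to
#' \[0, 360); a bare `atan(b/a)` would silently flip colors with negative
#' `a` into the wrong quadrant.
#'
#' @inheritParams chroma
#' @return Hue angle in degrees, in \[0, 360).
#' @examples
#' hue_angle(color_point(21.03, 2.65, 6.23))  # 66.96
#' @export
hue_angle <- function(color, a = NULL, b = NULL) {
  ab <- if (inherits(color, "color_point")) c(color$a, color$b) else c(color, a)
  if (ab[1] == 0 && ab[2] == 0)
    stop("hue angle undefined at a = b = 0")
  (atan2(ab[2], ab[1]) * 180 / pi) %% 360
}

#' Total color difference (delta E)
#'
#' Euclidean distance between two CIELAB points:
#' `sqrt(dL^2 + da^2 + db^2)`.  The reference color is caller-supplied;
#' no default reference is assumed.
#'
#' @param c1,c2 [color_point()] objects.
#' @return Delta E.
#' @export
delta_e <- function(c1, c2) {
  stopifnot(inherits(c1, "color_point"), inherits(c2, "color_point"))
  sqrt((c1$L - c2$L)^2 + (c1$a - c2$a)^2 + (c1$b - c2$b)^2)
}

#' Compute chroma and hue for a table of color measurements
#'
#' @param colors data.frame with columns `sample, L, a, b` (as read from a
#'   CSV by [read_color_table()]).
#' @return data.frame `sample, C, h`.
#' @export
color_metrics <- function(colors) {
  stopifnot(all(c("sample", "L", "a", "b") %in% names(colors)))
  data.frame(
    sample = colors$sample,
    C = sqrt(colors$a^2 + colors$b^2),
    h = (atan2(colors$b, colors$a) * 180 / pi) %% 360
  )
}

#' Read a color table CSV (`sample,L,a,b`)
#'
#' @param path CSV path.
#' @return data.frame with columns `sample, L, a, b`.
#' @export
read_color_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("sample", "L", "a", "b")
  if (!all(need %in% names(tab)))
    stop("color table must have columns ", paste(need, collapse = ", "))
  tab[need]
}
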