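# Registry of the published second-order sensory models for the three
# bulgur-pilaf varieties (taste, color, smell, general acceptance each).
# Coefficients are transcribed verbatim, anomalies included:
#   * the Siyez general-acceptance equation prints TWO X1*X2 monomials
#     (-0.004444 and +0.002299) and no X1^2 term; the as-printed form is
#     kept because the published optimum table is reproducible only from it.
#     A "corrected" variant reading the first cross term as X1^2 is provided
#     but never used for validation.
#   * the Siyez taste equation's constant/linear terms give values far off
#     the hedonic scale over much of the region (e.g. 125.1 at (150, 425));
#     stored as printed.

.registry <- list(
  siyez = list(
    taste  = c(-171.9, 2.298, -0.1073, -0.004678, -0.000283, 0.002420),
    color  = c(28.3, -0.977, 0.2183, 0.005856, 0.000014, -0.001593),
    smell  = c(153.8, -1.744, -0.1675, 0.008797, 0.000472, -0.001520),
    general_acceptance = data.frame(
      coef = c(-0.6, 0.354, -0.1019, -0.004444, -0.000269, 0.002299),
      p1   = c(0, 1, 0, 1, 0, 1),
      p2   = c(0, 0, 1, 1, 2, 1))
  ),
  firik = list(
    taste  = c(-171.9, 2.298, 0.0935, -0.009795, -0.000316, 0.001122),
    color  = c(159.0, -2.200, -0.0015, 0.006303, -0.000171, 0.001075),
    smell  = c(397.6, -3.481, -0.8012, 0.008632, 0.000504, 0.002964),
    general_acceptance = c(519.4, -3.620, -1.3146, 0.001766, 0.000293, 0.007817)
  ),
  karakilcik = list(
    taste  = c(-73.69, 1.5937, -0.16647, -0.007803, -0.000033, 0.001464),
    color  = c(-193.2, 2.476, 0.1047, -0.009512, -0.000214, 0.000580),
    smell  = c(145.54, -0.5278, -0.5358, -0.004189, -0.000073, 0.004343),
    general_acceptance = c(-259.5, 3.727, -0.0068, -0.014254, -0.000108, 0.000789)
  )
)

#' Varieties and responses covered by the published model registry
#'
#' @return Character vectors of valid names.
#' @export
registry_varieties <- function() names(.registry)

#' @rdname registry_varieties
#' @export
registry_responses <- function() c("taste", "color", "smell",
                                   "general_acceptance")

#' Retrieve a published sensory response surface
#'
#' Returns one of the twelve published second-order polynomials (three
#' bulgur varieties x four sensory responses), in natural units (X1 bulgur
#' g, X2 water mL).
#'
#' `form = "printed"` (default) keeps the equations exactly as published,
#' including the duplicated `X1*X2` monomial of the Siyez
#' general-acceptance model; `"merged"` collapses duplicate monomials to
#' the canonical six coefficients (identical evaluations); `"corrected"`
#' reinterprets the duplicated first cross term of that one equation as the
#' missing `X1^2` term.  The corrected form is an editorial conjecture and
#' is never used by the validation pipeline.
#'
#' @param variety `"siyez"`, `"firik"` or `"karakilcik"`.
#' @param response `"taste"`, `"color"`, `"smell"` or
#'   `"general_acceptance"`.
#' @param form `"printed"`, `"merged"` or `"corrected"`.
#' @return A `poly_surface` with provenance `"printed"`.
#' @examples
#' evaluate_surface(printed_model("firik", "taste"), 140, 400)  # 7.51
#' @export
printed_model <- function(variety, response,
                          form = c("printed", "merged", "corrected")) {
  form <- match.arg(form)
  variety <- match.arg(variety, registry_varieties())
  response <- match.arg(response, registry_responses())
  entry <- .registry[[variety]][[response]]
  label <- paste(variety, response)
  s <- if (is.data.frame(entry))
         poly_surface(terms = entry, label = label, provenance = "printed")
       else poly_surface(entry, label = label, provenance = "printed")
  if (form == "merged") return(merge_surface(s))
  if (form == "corrected") {
    if (is.data.frame(entry)) {
      co <- c(entry$coef[1:3], entry$coef[4], entry$coef[5], entry$coef[6])
      names(co) <- NULL  # first cross term re-read as the X1^2 coefficient
      s <- poly_surface(co, label = paste(label, "(corrected)"),
                        provenance = "printed")
    }
    return(s)
  }
  s
}

#' All twelve published surfaces as a named list
#'
#' @inheritParams printed_model
#' @return Named list `"<variety>.<response>"` of `poly_surface` objects.
#' @export
registry_surfaces <- function(form = c("printed", "merged", "corrected")) {
  form <- match.arg(form)
  out <- list()
  for (v in registry_varieties())
    for (r in registry_responses())
      out[[paste(v, r, sep = ".")]] <- printed_model(v, r, form)
  out
}

#' Search rectangles for surface optimisation
#'
#' `reproduction_bounds()` is the rectangle X1 in \[135, 150\] g, X2 in
#' \[375, 425\] mL: every published optimum (including the exact boundary
#' coordinates 135/150/375/425) is consistent with this domain, although
#' the source never states its search bounds.  `experimental_bounds()` is
#' the full experimental region X1 in \[130, 150\], X2 in \[350, 450\]
#' actually spanned by the design's axial points.
#'
#' @return `list(x1 = c(lo, hi), x2 = c(lo, hi))`.
#' @export
reproduction_bounds <- function() list(x1 = c(135, 150), x2 = c(375, 425))

#' @rdname reproduction_bounds
#' @export
experimental_bounds <- function() list(x1 = c(130, 150), x2 = c(350, 450))
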