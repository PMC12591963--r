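#' Specify a design factor
#'
#' A factor in a central composite design (CCD), holding the mapping between
#' coded design levels (\eqn{-\alpha \dots +\alpha}) and natural units
#' (grams, millilitres, ...).  When an explicit `levels` map is given it
#' overrides linear coding: published designs frequently round their axial
#' naturals to convenient values (e.g. 130/150 g where \eqn{\pm 1.41} linear
#' steps of 5 g would give 132.95/147.05), and only the explicit map
#' reproduces the printed design exactly.
#'
#' @param name Factor label, e.g. `"bulgur_g"`.
#' @param center Natural value at coded level 0.
#' @param step Natural units per coded unit (linear fallback scaling).
#' @param levels Optional named-by-nothing two-column `data.frame` with
#'   columns `coded` and `natural`, or a numeric vector of natural values
#'   whose names are coded levels.  Must be strictly increasing in the coded
#'   level and consistent with `center` at coded 0.
#' @param bounds Length-2 numeric `c(low, high)` in natural units.  Defaults
#'   to the range of `levels` when given, else `center +/- 1.41 * step`.
#' @return An object of class `factor_spec`.
#' @examples
#' bulgur <- factor_spec("bulgur_g", center = 140, step = 5,
#'                       levels = c(`-1.41` = 130, `-1` = 135, `0` = 140,
#'                                  `1` = 145, `1.41` = 150))
#' code_to_natural(1.41, bulgur)  # 150 (map lookup, not 147.05)
#' @export
factor_spec <- function(name, center, step, levels = NULL, bounds = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(step), length(step) == 1L, is.finite(step), step > 0)
  level_map <- NULL
  if (!is.null(levels)) {
    if (is.numeric(levels) && !is.null(names(levels))) {
      level_map <- data.frame(coded = as.numeric(names(levels)),
                              natural = as.numeric(levels))
    } else if (is.data.frame(levels)) {
      stopifnot(all(c("coded", "natural") %in% names(levels)))
      level_map <- data.frame(coded = as.numeric(levels$coded),
                              natural = as.numeric(levels$natural))
    } else {
      stop("`levels` must be a named numeric vector or a data.frame with ",
           "columns `coded` and `natural`")
    }
    level_map <- level_map[order(level_map$coded), , drop = FALSE]
    if (anyDuplicated(level_map$coded))
      stop("duplicate coded levels in `levels` for factor ", name)
    if (any(diff(level_map$natural) <= 0))
      stop("`levels` for factor ", name,
           " is not strictly monotone in the coded level")
    i0 <- which(abs(level_map$coded) < 1e-12)
    if (length(i0) == 1L && abs(level_map$natural[i0] - center) > 1e-9)
      stop("`center` (", center, ") disagrees with the natural value mapped ",
           "from coded 0 (", level_map$natural[i0], ") for factor ", name)
  }
  if (is.null(bounds)) {
    bounds <- if (!is.null(level_map)) range(level_map$natural)
              else center + c(-1.41, 1.41) * step
  }
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  structure(list(name = name, center = center, step = step,
                 level_map = level_map,
                 low_bound = bounds[1], high_bound = bounds[2]),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat("<factor_spec> ", x$name, ": center ", x$center, ", step ", x$step,
      ", bounds [", x$low_bound, ", ", x$high_bound, "]\n", sep = "")
  if (!is.null(x$level_map)) {
    cat("  levels: ",
        paste0(x$level_map$coded, " -> ", x$level_map$natural,
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Convert coded design levels to natural units
#'
#' Exact design levels are looked up in the factor's level map when one is
#' present; any other level falls back to the linear coding
#' `center + level * step`.  Levels outside the hull of the map's coded keys
#' are rejected.
#'
#' @param level Numeric vector of coded levels.
#' @param factor A [factor_spec()].
#' @return Numeric vector of natural values.
#' @seealso [natural_to_code()]
#' @export
code_to_natural <- function(level, factor) {
  stopifnot(inherits(factor, "factor_spec"), is.numeric(level))
  lm <- factor$level_map
  if (is.null(lm)) return(factor$center + level * factor$step)
  hull <- range(lm$coded)
  if (any(level < hull[1] - 1e-9 | level > hull[2] + 1e-9))
    stop("coded level outside the hull [", hull[1], ", ", hull[2],
         "] of the level map for factor ", factor$name)
  vapply(level, function(l) {
    hit <- which(abs(lm$coded - l) < 1e-9)
    if (length(hit) == 1L) lm$natural[hit] else factor$center + l * factor$step
  }, numeric(1))
}

#' Convert natural units back to coded design levels
#'
#' Inverse of [code_to_natural()]: exact design naturals are looked up in
#' the level map; other values use the linear coding
#' `(value - center) / step`.
#'
#' @param value Numeric vector of natural values.
#' @param factor A [factor_spec()].
#' @return Numeric vector of coded levels.
#' @export
natural_to_code <- function(value, factor) {
  stopifnot(inherits(factor, "factor_spec"), is.numeric(value))
  lm <- factor$level_map
  if (is.null(lm)) return((value - factor$center) / factor$step)
  vapply(value, function(v) {
    hit <- which(abs(lm$natural - v) < 1e-9)
    if (length(hit) == 1L) lm$coded[hit] else (v - factor$center) / factor$step
  }, numeric(1))
}

#' Build a two-factor central composite design
#'
#' Constructs the standard face of a two-factor CCD: 4 factorial points at
#' coded \eqn{(\pm 1, \pm 1)}, 4 axial points at \eqn{(\pm\alpha, 0)} and
#' \eqn{(0, \pm\alpha)}, and `n_center` replicated centre points at (0, 0).
#' Run order is deterministic (factorial, axial, centre) unless a
#' `permute_seed` is supplied.
#'
#' @param factors List of exactly two [factor_spec()] objects.
#' @param n_center Number of centre replicates (>= 1).
#' @param alpha Axial distance in coded units (> 1).  The conventional
#'   rotatable value for two factors is \eqn{\sqrt 2}; published designs
#'   often use the two-decimal rounding 1.41, which is the default.
#' @param constants Named list of fixed ingredients carried along with the
#'   design (written to a JSON sidecar by [write_design()]).
#' @param permute_seed Optional integer; when given, rows are randomised
#'   with this seed.
#' @return A `ccd_design`: list with elements `factors`, `design`
#'   (data.frame `run, x1_coded, x2_coded, x1_natural, x2_natural`),
#'   `n_center` and `constants`.
#' @examples
#' d <- build_ccd(list(factor_spec("x1", 0, 1), factor_spec("x2", 0, 1)),
#'                n_center = 1)
#' nrow(d$design)  # 9
#' @export
build_ccd <- function(factors, n_center = 5, alpha = 1.41,
                      constants = list(), permute_seed = NULL) {
  if (length(factors) != 2L || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("`factors` must be a list of exactly two factor_spec objects")
  stopifnot(n_center >= 1, alpha > 1)
  coded <- rbind(
    cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1)),          # factorial
    cbind(c(-alpha, alpha, 0, 0), c(0, 0, -alpha, alpha)),  # axial
    matrix(0, nrow = n_center, ncol = 2)              # centre replicates
  )
  if (!is.null(permute_seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(permute_seed)
    coded <- coded[sample.int(nrow(coded)), , drop = FALSE]
  }
  design <- data.frame(
    run = seq_len(nrow(coded)),
    x1_coded = coded[, 1], x2_coded = coded[, 2],
    x1_natural = code_to_natural(coded[, 1], factors[[1]]),
    x2_natural = code_to_natural(coded[, 2], factors[[2]])
  )
  structure(list(factors = factors, design = design,
                 n_center = as.integer(n_center), constants = constants),
            class = "ccd_design")
}

#' @export
print.ccd_design <- function(x, ...) {
  cat("<ccd_design> ", nrow(x$design), " runs (", x$n_center,
      " centre replicates), factors: ",
      paste(vapply(x$factors, `[[`, "", "name"), collapse = ", "), "\n",
      sep = "")
  print(x$design, row.names = FALSE)
  invisible(x)
}

#' The published 13-run bulgur-pilaf formulation design
#'
#' The five-level, two-factor CCD used for all three bulgur varieties:
#' bulgur amount X1 in {130, 135, 140, 145, 150} g and water amount X2 in
#' {350, 375, 400, 425, 450} mL, with 5 centre replicates at (140 g, 400
#' mL) and fixed butter (14 g) and salt (2 g).  Rows follow the published
#' run listing, not the factorial/axial/centre construction order.
#'
#' @return A `ccd_design` with 13 rows.
#' @export
pilaf_design <- function() {
  f1 <- factor_spec("bulgur_g", center = 140, step = 5,
                    levels = c(`-1.41` = 130, `-1` = 135, `0` = 140,
                               `1` = 145, `1.41` = 150))
  f2 <- factor_spec("water_mL", center = 400, step = 25,
                    levels = c(`-1.41` = 350, `-1` = 375, `0` = 400,
                               `1` = 425, `1.41` = 450))
  coded <- rbind(c(0, 0), c(1.41, 0), c(0, 0), c(0, 0), c(-1, 1), c(1, 1),
                 c(1, -1), c(0, -1.41), c(0, 1.41), c(0, 0), c(-1, -1),
                 c(0, 0), c(-1.41, 0))
  design <- data.frame(
    run = seq_len(nrow(coded)),
    x1_coded = coded[, 1], x2_coded = coded[, 2],
    x1_natural = code_to_natural(coded[, 1], f1),
    x2_natural = code_to_natural(coded[, 2], f2)
  )
  structure(list(factors = list(f1, f2), design = design, n_center = 5L,
                 constants = list(butter_g = 14, salt_g = 2)),
            class = "ccd_design")
}

#' Write / read a design table as delimited text
#'
#' Designs are stored as CSV with header
#' `run,x1_coded,x2_coded,x1_natural,x2_natural`; factor metadata and fixed
#' ingredients go to a JSON sidecar `<path>.json`.
#'
#' @param design A `ccd_design`.
#' @param path Output CSV path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a `ccd_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ccd_design"))
  utils::write.csv(design$design, path, row.names = FALSE, quote = FALSE)
  side <- list(
    factors = lapply(design$factors, function(f) {
      out <- list(name = f$name, center = f$center, step = f$step,
                  low_bound = f$low_bound, high_bound = f$high_bound)
      if (!is.null(f$level_map)) out$level_map <- f$level_map
      out
    }),
    n_center = design$n_center,
    constants = design$constants
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("run", "x1_coded", "x2_coded", "x1_natural", "x2_natural")
  if (!all(need %in% names(tab)))
    stop("design CSV must have columns ", paste(need, collapse = ", "))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  factors <- lapply(side$factors, function(f) {
    lv <- if (!is.null(f$level_map)) {
      data.frame(coded = vapply(f$level_map, function(r) r$coded, 0),
                 natural = vapply(f$level_map, function(r) r$natural, 0))
    }
    factor_spec(f$name, f$center, f$step, levels = lv,
                bounds = c(f$low_bound, f$high_bound))
  })
  structure(list(factors = factors, design = tab[need],
                 n_center = as.integer(side$n_center),
                 constants = as.list(side$constants)),
            class = "ccd_design")
}

# Save/restore the global RNG state so helpers that seed internally do not
# disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
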