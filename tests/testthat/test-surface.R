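test_that("evaluate_surface matches published table values", {
  # predicted value at the centre run, and best scores at published optima
  expect_equal(evaluate_surface(printed_model("firik", "taste"), 140, 400),
               7.51, tolerance = 0.005)
  expect_equal(evaluate_surface(printed_model("karakilcik", "smell"),
                                150, 425), 8.083, tolerance = 0.005)
  # as-printed duplicated cross terms (two X1*X2 monomials) sum on evaluation
  s9 <- printed_model("siyez", "general_acceptance")
  expect_equal(nrow(s9$terms), 6L)
  expect_equal(sum(s9$terms$p1 == 1 & s9$terms$p2 == 1), 2L)
  expect_equal(evaluate_surface(s9, 135, 375), -137.441, tolerance = 0.005)
  expect_equal(evaluate_surface(poly_surface(rep(0, 6)), 3, -7), 0)
})

test_that("registry returns verbatim coefficients and a merged view", {
  s <- printed_model("siyez", "taste")
  expect_equal(unname(coef(s)),
               c(-171.9, 2.298, -0.1073, -0.004678, -0.000283, 0.002420))
  expect_equal(unname(coef(printed_model("karakilcik",
                                         "general_acceptance"))[1:2]),
               c(-259.5, 3.727))
  merged <- printed_model("siyez", "general_acceptance", form = "merged")
  expect_equal(unname(coef(merged)["b12"]), -0.004444 + 0.002299)
  expect_equal(nrow(merged$terms), 6L)
  expect_error(printed_model("emmer", "taste"))
  expect_error(printed_model("siyez", "aroma"))
  expect_length(registry_surfaces(), 12L)
})

test_that("merged and as-printed representations evaluate identically", {
  pts <- expand.grid(x1 = c(130, 137.5, 150), x2 = c(350, 401, 450))
  for (s in registry_surfaces()) {
    m <- merge_surface(s)
    expect_equal(evaluate_surface(s, pts$x1, pts$x2),
                 evaluate_surface(m, pts$x1, pts$x2))
  }
})

test_that("corrected registry variant re-reads the duplicate cross term as X1^2", {
  s <- printed_model("siyez", "general_acceptance", form = "corrected")
  co <- coef(s)
  expect_equal(unname(co["b11"]), -0.004444)
  expect_equal(unname(co["b12"]), 0.002299)
  # corrected form is a different surface from the as-printed one
  expect_false(isTRUE(all.equal(
    evaluate_surface(s, 135, 375),
    evaluate_surface(printed_model("siyez", "general_acceptance"), 135, 375))))
  # varieties without the anomaly are unchanged
  expect_equal(coef(printed_model("firik", "taste", "corrected")),
               coef(printed_model("firik", "taste")))
})

test_that("stationary_point solves and classifies the gradient system", {
  sp <- stationary_point(printed_model("firik", "taste"))
  expect_equal(sp$x1, 140.014, tolerance = 1e-3)
  expect_equal(sp$x2, 396.52, tolerance = 1e-4)
  expect_equal(sp$value, 7.514, tolerance = 0.005)
  expect_identical(sp$classification, "maximum")
  # published Karakilcik taste surface has an indefinite Hessian
  expect_identical(stationary_point(printed_model("karakilcik",
                                                  "taste"))$classification,
                   "saddle")
  expect_identical(
    stationary_point(poly_surface(c(0, 0, 0, -1, -1, 0)))$classification,
    "maximum")
  expect_equal(stationary_point(poly_surface(c(0, 0, 0, -1, -1, 0)))$x1, 0)
  expect_identical(
    stationary_point(poly_surface(c(1, 2, 3, 0, 0, 0)))$classification,
    "degenerate")
})

test_that("bounded_optimum reproduces published constrained optima", {
  rect <- reproduction_bounds()
  opt <- bounded_optimum(printed_model("karakilcik", "taste"), rect)
  expect_equal(opt$x1, 141.990, tolerance = 1e-5)
  expect_equal(opt$x2, 425)
  expect_equal(opt$value, 6.918, tolerance = 0.005)
  opt8 <- bounded_optimum(printed_model("siyez", "smell"), rect)
  expect_equal(c(opt8$x1, opt8$x2), c(150, 375))
  expect_equal(opt8$value, 8.195, tolerance = 0.005)
  # linear surface maximum lands on a corner
  lin <- bounded_optimum(poly_surface(c(0, 1, -2, 0, 0, 0)),
                         list(x1 = c(0, 1), x2 = c(0, 1)), grid_step = 0.1)
  expect_equal(c(lin$x1, lin$x2), c(1, 0))
  expect_error(bounded_optimum(lin, list(x1 = c(1, 0), x2 = c(0, 1))),
               "rectangle")
})

test_that("grid oracle agrees with the analytic interior maximum", {
  set.seed(42)
  for (i in 1:8) {
    # random concave quadratic with stationary point inside the unit box
    b11 <- -runif(1, 0.5, 2); b22 <- -runif(1, 0.5, 2)
    b12 <- runif(1, -0.5, 0.5)
    x0 <- runif(2, 0.25, 0.75)
    b1 <- -(2 * b11 * x0[1] + b12 * x0[2])
    b2 <- -(2 * b22 * x0[2] + b12 * x0[1])
    s <- poly_surface(c(0, b1, b2, b11, b22, b12))
    sp <- stationary_point(s)
    expect_identical(sp$classification, "maximum")
    opt <- bounded_optimum(s, list(x1 = c(0, 1), x2 = c(0, 1)),
                           grid_step = 0.05, refine_step = 0.001)
    expect_equal(c(opt$x1, opt$x2), c(sp$x1, sp$x2), tolerance = 2e-3)
    expect_equal(opt$value, sp$value, tolerance = 1e-5)
  }
})

test_that("percent_difference supports both denominator conventions", {
  expect_equal(percent_difference(7.67, 7.83), 2.04, tolerance = 0.005)
  # published Firik taste validation cell (printed as 6.17)
  expect_equal(percent_difference(6.68, 7.12), 6.18, tolerance = 0.005)
  expect_equal(percent_difference(5, 5), 0)
  # the one published cell consistent with a predicted-value denominator
  expect_equal(percent_difference(7.75, 7.50, denominator = "predicted"),
               3.22, tolerance = 0.005)
  expect_error(percent_difference(1, 0), "denominator")
})

test_that("surfaces serialize to JSON term lists and back", {
  path <- withr::local_tempfile(fileext = ".json")
  s <- printed_model("siyez", "general_acceptance")
  write_surface(s, path)
  s2 <- read_surface(path)
  expect_equal(s2$terms, s$terms)
  expect_identical(s2$provenance, "printed")
  expect_equal(evaluate_surface(s2, 135, 375),
               evaluate_surface(s, 135, 375))
})

test_that("degree > 2 terms are rejected", {
  expect_error(poly_surface(terms = data.frame(coef = 1, p1 = 2, p2 = 1)),
               "degree")
})
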