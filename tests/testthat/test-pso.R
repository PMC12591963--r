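test_that("inertia weight decays linearly from w_start to w_end", {
  cfg <- swarm_config()
  expect_equal(inertia_at(0, cfg), 0.90)
  expect_equal(inertia_at(39, cfg), 0.30)
  # linearity: midpoint of an odd-length schedule is the mean of endpoints
  cfg41 <- swarm_config(iterations = 41)
  expect_equal(inertia_at(20, cfg41), 0.60)
  expect_error(inertia_at(40, cfg), "out of range")
  expect_error(inertia_at(-1, cfg), "out of range")
  expect_equal(inertia_at(0, swarm_config(iterations = 1)), 0.90)
})

test_that("update_particle follows the velocity/position equations", {
  # hand arithmetic: v' = 0.9*1 + 0.1*1*(145-140) + 0.1*1*(150-140) = 2.4
  up <- update_particle(c(140, 400), c(1, 0), pbest = c(145, 400),
                        gbest = c(150, 400), w = 0.9, c1 = 0.1, c2 = 0.1,
                        r1 = 1, r2 = 1)
  expect_equal(up$velocity, c(2.4, 0))
  expect_equal(up$position, c(142.4, 400))
  # c1 = c2 = 0, w = 1: pure drift
  up2 <- update_particle(c(1, 2), c(0.5, -0.5), c(0, 0), c(9, 9),
                         w = 1, c1 = 0, c2 = 0, r1 = 0.3, r2 = 0.8)
  expect_equal(up2$velocity, c(0.5, -0.5))
  expect_equal(up2$position, c(1.5, 1.5))
  # x = pbest = gbest: both attraction terms vanish
  up3 <- update_particle(c(2, 2), c(1, 1), c(2, 2), c(2, 2),
                         w = 0.7, c1 = 0.1, c2 = 0.1, r1 = 1, r2 = 1)
  expect_equal(up3$velocity, c(0.7, 0.7))
  # clamping pins the position, not the velocity
  up4 <- update_particle(c(0.9, 0.5), c(0.5, 0), c(0.9, 0.5), c(0.9, 0.5),
                         w = 1, c1 = 0, c2 = 0, r1 = 0, r2 = 0,
                         bounds = list(x1 = c(0, 1), x2 = c(0, 1)))
  expect_equal(up4$position, c(1, 0.5))
  expect_equal(up4$velocity, c(0.5, 0))
  expect_error(update_particle(c(0, 0), c(0, 0), c(0, 0), c(0, 0),
                               1, 1, 1, r1 = 1.5, r2 = 0))
})

test_that("a constant objective never improves past iteration 0", {
  cfg <- swarm_config(n_runs = 1, seed = 5)
  tr <- pso_maximize(function(x1, x2) rep(3.25, length(x1)), cfg)
  expect_equal(tr$best_score, 3.25)
  expect_equal(unique(tr$trace$best_score), 3.25)
})

test_that("same seed and config give identical traces; seeds differ", {
  s <- printed_model("firik", "color")
  cfg <- swarm_config(seed = 7)
  t1 <- pso_maximize(s, cfg)
  t2 <- pso_maximize(s, cfg)
  expect_identical(t1, t2)
  t3 <- pso_maximize(s, cfg, run_seed = 8)
  expect_false(identical(t1$trace, t3$trace))
})

test_that("multi_run serialization is byte-identical under a fixed master seed", {
  s <- printed_model("karakilcik", "color")
  cfg <- swarm_config(n_runs = 4, seed = 123)
  m1 <- multi_run(s, cfg)
  m2 <- multi_run(s, cfg)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("best-so-far traces are monotone and positions stay in bounds", {
  cfg <- swarm_config(n_runs = 3, seed = 31)
  b <- cfg$bounds
  for (s in registry_surfaces()[c(1, 4, 9)]) {
    mr <- multi_run(s, cfg)
    for (tr in mr$traces) {
      expect_true(all(diff(tr$trace$best_score) >= 0))
      expect_true(all(tr$trace$best_x1 >= b[1, 1] &
                        tr$trace$best_x1 <= b[1, 2]))
      expect_true(all(tr$trace$best_x2 >= b[2, 1] &
                        tr$trace$best_x2 <= b[2, 2]))
    }
    expect_lte(mr$mean, mr$best_score)
    expect_gte(mr$sd, 0)
  }
})

test_that("single-run summary reports sd = 0 with a flag", {
  mr <- multi_run(printed_model("siyez", "color"),
                  swarm_config(n_runs = 1, seed = 2))
  expect_equal(mr$sd, 0)
  expect_true(mr$single_run)
})

test_that("swarm finds the published Firik taste interior optimum", {
  mr <- multi_run(printed_model("firik", "taste"), swarm_config(seed = 10))
  expect_equal(mr$best_score, 7.514, tolerance = 2e-3)
  expect_equal(mr$best_position[1], 140.0, tolerance = 1e-3)
  expect_equal(mr$best_position[2], 396.5, tolerance = 1e-3)
  expect_lt(mr$sd, 0.01)
})

test_that("velocity clamp caps particle speed", {
  s <- printed_model("firik", "smell")
  # a zero clamp freezes the swarm at its initial sample
  frozen <- pso_maximize(s, swarm_config(n_runs = 1, seed = 3,
                                         velocity_clamp = 0))
  expect_equal(unique(frozen$trace$best_score), frozen$trace$best_score[1])
  # a finite clamp changes the dynamics relative to the unclamped default
  clamped <- pso_maximize(s, swarm_config(n_runs = 1, seed = 3,
                                          velocity_clamp = 0.02))
  free <- pso_maximize(s, swarm_config(n_runs = 1, seed = 3))
  expect_false(identical(clamped$trace, free$trace))
})

test_that("non-finite objective aborts with the offending position", {
  bad <- function(x1, x2) ifelse(x1 > 140, NaN, x1)
  expect_error(pso_maximize(bad, swarm_config(seed = 1)), "non-finite")
})

test_that("traces and contour grids export to delimited text", {
  tr <- pso_maximize(printed_model("firik", "taste"),
                     swarm_config(seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("iteration", "best_x1", "best_x2", "best_score"))
  expect_equal(nrow(back), 41L)
  g <- contour_grid(printed_model("firik", "taste"), n = 11)
  expect_equal(nrow(g), 121L)
  expect_equal(g$predicted,
               evaluate_surface(printed_model("firik", "taste"), g$x1, g$x2))
})
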