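test_that("body diameter follows the body-to-neck definition for all four sizes", {
  for (bnr in c(2.2, 3, 5.4, 8)) {
    g <- build_ma_channel(bnr, r2 = 5)
    expect_identical(g$R1, bnr * 5)
    expect_identical(g$R1 / g$r2, bnr)
  }
  expect_equal(build_ma_channel(2.2)$R1, 11)
  expect_equal(build_ma_channel(8)$R1, 40)
  expect_error(build_ma_channel(3, neck_width = 20), "wider than the body")
})

test_that("a unit body-to-neck ratio degenerates to a watertight hemispherical pocket", {
  g <- build_ma_channel(1, r2 = 5, neck_width = 5)
  expect_equal(g$yc, g$r2) # body centre on the wall plane
  set.seed(2)
  pts <- cbind(runif(20000, 0, g$length), runif(20000, -2, g$yc + g$R + 2),
               runif(20000, -2, g$depth + 2))
  cl <- classify_point(g, pts)
  # watertight: every body point sits inside the disc, every path from
  # parent to body crosses y = r2 within the neck
  body <- cl == "ma_body"
  expect_true(all(pts[body, 2] > g$r2))
  expect_true(all((pts[body, 1] - g$xc)^2 + (pts[body, 2] - g$yc)^2 <=
                    g$R^2 + 1e-9))
})

test_that("point classification agrees with a constructive-solid-geometry oracle", {
  g <- build_ma_channel(5.4, length = 60)
  set.seed(31)
  n <- 1e5
  pts <- cbind(runif(n, 0, g$length), runif(n, -2, g$yc + g$R + 2),
               runif(n, -2, g$depth + 2))
  csg <- function(p) {
    in_z <- p[, 3] >= 0 & p[, 3] <= g$depth
    in_duct <- p[, 2] >= 0 & p[, 2] <= g$r2
    in_disc <- (p[, 1] - g$xc)^2 + (p[, 2] - g$yc)^2 <= g$R^2 & p[, 2] > g$r2
    ifelse(!in_z, "outside",
           ifelse(in_duct, "parent", ifelse(in_disc, "ma_body", "outside")))
  }
  expect_identical(classify_point(g, pts), csg(pts))
  # centreline and body centre land where they must
  expect_identical(classify_point(g, c(5, 2.5, 5)), "parent")
  expect_identical(classify_point(g, c(g$xc, g$yc, 5)), "ma_body")
})

test_that("analytic lumen volume matches a Monte-Carlo estimate within 1 percent", {
  for (bnr in c(2.2, 5.4)) {
    g <- build_ma_channel(bnr, length = 50)
    set.seed(5)
    n <- 2e5
    ymax <- g$yc + g$R + 1
    pts <- cbind(runif(n, 0, g$length), runif(n, -1, ymax),
                 runif(n, -1, g$depth + 1))
    frac <- mean(classify_point(g, pts) != "outside")
    vol_mc <- frac * g$length * (ymax + 1) * (g$depth + 2)
    expect_equal(vol_mc, g$lumen_volume, tolerance = 0.01)
  }
})

test_that("wall particles lie outside the lumen within the shell, and thin shells error", {
  g <- build_ma_channel(3, length = 40)
  w <- generate_wall_particles(g, thickness = 1, density = 2, rc = 1, seed = 3)
  expect_gt(nrow(w), 100)
  expect_true(all(classify_point(g, w) == "outside"))
  d <- mavessel:::cpp_lumen_distance(mavessel:::as_geom_vec(g), w)
  expect_true(all(d > 0 & d <= 1 + 1e-9))
  expect_error(generate_wall_particles(g, thickness = 0.5, rc = 1),
               "thinner than")
  # doubling the density roughly doubles the particle count at fixed shell
  w2 <- generate_wall_particles(g, thickness = 1, density = 4, rc = 1, seed = 3)
  expect_equal(nrow(w2) / nrow(w), 2, tolerance = 0.15)
})

test_that("pulsatile modulation has unit mean and the stated instantaneous values", {
  d0 <- flow_drive(1.5, "static")
  expect_equal(pulsatile_modulation(d0, c(0, 0.3, 2)), c(1, 1, 1))
  d <- flow_drive(1.5, "pulsatile", amplitude = 0.4, period_s = 1)
  expect_equal(pulsatile_modulation(d, 0.25), 1.4)
  ts <- seq(0, 1, length.out = 2001)[-2001]
  expect_equal(mean(pulsatile_modulation(d, ts)), 1, tolerance = 1e-9)
  expect_error(flow_drive(1.5, "pulsatile", period_s = 0), "period")
  expect_error(pulsatile_modulation(d, 0.1, period = -1), "positive")
})

test_that("the body-force controller is fixed at the target and recovers stalled flow", {
  # steady at target: no change
  st <- list(g = 0.2, v_prev = 0.5)
  out <- body_force_controller(st, target = 0.5, measured = 0.5,
                               dt_window = 1)
  expect_equal(out$g, 0.2)
  # stalled flow with a positive target: force must grow
  st2 <- list(g = 0.1, v_prev = NA_real_)
  out2 <- body_force_controller(st2, target = 0.5, measured = 0)
  expect_gt(out2$g, 0.1)
  # non-finite measurement: hold
  out3 <- body_force_controller(list(g = 0.3, v_prev = 0.2), 0.5, NaN)
  expect_equal(out3$g, 0.3)
  # overshoot: force must come down
  out4 <- body_force_controller(list(g = 0.4, v_prev = 1.0), 0.5, 1.0,
                                dt_window = 1)
  expect_lt(out4$g, 0.4)
})

test_that("config YAML round trip preserves the scenario definition", {
  cfg <- make_mini_ma(5.4, hematocrit = 0.2, adhesion = TRUE, seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  cfg2 <- read_config_yaml(path)
  expect_equal(cfg2$geometry$R1, cfg$geometry$R1)
  expect_equal(cfg2$hematocrit, cfg$hematocrit)
  expect_true(cfg2$morse$enabled)
  expect_equal(cfg2$drive$target_mm_s, cfg$drive$target_mm_s)
  expect_equal(cfg2$steps, cfg$steps)
})
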