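g_test <- build_ma_channel(5.4, length = 60)

mk_track <- function(regions, xs = NULL, dt = 0.005, born_inside = FALSE) {
  n <- length(regions)
  if (is.null(xs)) {
    # put body frames near the neck, parent frames marching through it
    xs <- seq(g_test$xc - g_test$h - 6, g_test$xc + g_test$h + 6,
              length.out = n)
  }
  data.frame(cell = 1, type = "platelet", frame = seq_len(n) - 1,
             time = (seq_len(n) - 1) * dt, x = xs,
             y = 2.5, z = 5, region = regions, born_inside = born_inside)
}

test_that("a plain traversal yields one passage with no entry", {
  tr <- mk_track(rep("parent", 30))
  ev <- detect_events(tr, g_test)
  expect_equal(nrow(ev), 1)
  expect_false(ev$entered)
  expect_false(ev$censored)
})

test_that("residence time is the elapsed time between entry and exit", {
  tr <- mk_track(c(rep("parent", 10), rep("ma_body", 50), rep("parent", 10)))
  ev <- detect_events(tr, g_test)
  expect_equal(nrow(ev), 1)
  expect_true(ev$entered)
  # 50 body frames: first to last spans 49 intervals of 0.005 s, and the
  # recorded residence is t_exit - t_enter
  expect_equal(ev$residence, 49 * 0.005)
  expect_false(ev$censored)
})

test_that("single-frame blips are debounced and still-inside cells are censored", {
  blip <- mk_track(c(rep("parent", 10), "ma_body", rep("parent", 10)))
  ev <- detect_events(blip, g_test, debounce = 3)
  expect_true(all(!ev$entered))
  cens <- mk_track(c(rep("parent", 10), rep("ma_body", 10)))
  ev2 <- detect_events(cens, g_test)
  expect_true(ev2$entered[1])
  expect_true(ev2$censored[1])
  expect_true(is.na(ev2$residence[1]))
})

test_that("cells born inside the aneurysm are excluded from event detection", {
  tr <- mk_track(c(rep("ma_body", 20), rep("parent", 10)), born_inside = TRUE)
  expect_equal(nrow(detect_events(tr, g_test)), 0)
  short <- mk_track("parent")
  expect_equal(nrow(detect_events(short, g_test)), 0)
})

test_that("entry probability is the stated ratio with its edge cases", {
  rec <- data.frame(cell = rep(1:4, each = 3), type = "platelet",
                    entered = c(rep(TRUE, 3), rep(FALSE, 9)),
                    censored = FALSE, residence = NA)
  ep <- entry_probability(rec)
  expect_equal(ep$probability, 3 / 12)
  expect_equal(ep$n_passages, 12)
  rec0 <- transform(rec, entered = FALSE)
  expect_equal(entry_probability(rec0)$probability, 0)
  rec1 <- transform(rec, entered = TRUE)
  expect_equal(entry_probability(rec1)$probability, 1)
  expect_error(entry_probability(rec[0, ]), "no passages")
  # invariant to cell relabelling and row order
  perm <- rec[sample(nrow(rec)), ]
  perm$cell <- match(perm$cell, c(3, 1, 4, 2))
  expect_equal(entry_probability(perm)$probability, 3 / 12)
})

test_that("residence summaries separate censored events from the mean", {
  rec <- data.frame(cell = c(1, 2, 3, 4), type = "platelet",
                    entered = TRUE,
                    censored = c(FALSE, FALSE, FALSE, TRUE),
                    residence = c(0.25, 0.35, 0.30, NA))
  rs <- residence_summary(rec)
  expect_equal(rs$mean, 0.30)
  expect_equal(rs$n_events, 3)
  expect_equal(rs$n_censored, 1)
  only_cens <- rec[4, ]
  rs2 <- residence_summary(only_cens)
  expect_identical(rs2$status, "censored-only")
  expect_error(residence_summary(rec[0, ]), "no completed")
})

test_that("bootstrap interval covers the true mean of exponential residence times", {
  # estimator check against a known generating distribution
  set.seed(42)
  true_mean <- 0.3
  hits <- 0
  for (rep in 1:100) {
    n_cells <- 25
    rec <- data.frame(cell = seq_len(n_cells), type = "platelet",
                      entered = TRUE, censored = FALSE,
                      residence = rexp(n_cells, 1 / true_mean))
    rs <- residence_summary(rec, n_boot = 400, seed = rep)
    if (rs$ci[1] <= true_mean && true_mean <= rs$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("perfusion fraction is 0 with no body visits and approaches 1 when filled", {
  empty <- data.frame(cell = 1, type = "rbc", frame = 0:20, time = 0:20,
                      x = 5, y = 2.5, z = 5, region = "parent",
                      born_inside = FALSE)
  pm <- perfusion_map(empty, g_test, voxel = 2)
  expect_equal(pm$fraction, 0)
  # synthetic tracks filling the body uniformly
  set.seed(8)
  n <- 8000
  xs <- runif(n, g_test$xc - g_test$R, g_test$xc + g_test$R)
  ys <- runif(n, g_test$r2, g_test$yc + g_test$R)
  zs <- runif(n, 0, g_test$depth)
  keep <- classify_point(g_test, cbind(xs, ys, zs)) == "ma_body"
  fill <- data.frame(cell = 1, type = "rbc", frame = seq_len(sum(keep)),
                     time = 1, x = xs[keep], y = ys[keep], z = zs[keep],
                     region = "ma_body", born_inside = FALSE)
  pm2 <- perfusion_map(fill, g_test, voxel = 2)
  expect_gt(pm2$fraction, 0.9)
  expect_error(perfusion_map(fill, g_test, voxel = 30), "voxel")
})

test_that("metrics are invariant to frame-cadence refinement within one interval", {
  coarse <- mk_track(c(rep("parent", 8), rep("ma_body", 12), rep("parent", 8)),
                     dt = 0.01)
  fine_regions <- rep(coarse$region, each = 2)
  fine <- mk_track(fine_regions, dt = 0.005)
  ev_c <- detect_events(coarse, g_test)
  ev_f <- detect_events(fine, g_test)
  expect_equal(ev_f$residence, ev_c$residence, tolerance = 0.01 / ev_c$residence)
  expect_equal(sum(ev_f$entered), sum(ev_c$entered))
})
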