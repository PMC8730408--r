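test_that("fluctuation-dissipation holds by construction and bad params are rejected", {
  p <- dpd_params(a = 25, gamma = 4.5, kBT = 2)
  expect_equal(p$sigma^2, 2 * p$gamma * p$kBT)
  expect_error(dpd_params(rc = 0))
  expect_error(dpd_params(a = -1))
  expect_error(dpd_params(a = matrix(1:16, 4, 4)), "symmetric")
})

test_that("pair force vanishes beyond the cutoff and on coincident particles errors", {
  p <- dpd_params()
  pi_ <- list(pos = c(0, 0, 0), vel = c(1, 0, 0), type = "solvent")
  pj <- list(pos = c(1.01 * p$rc, 0, 0), vel = c(0, 0, 0), type = "solvent")
  expect_equal(pairwise_dpd_force(pi_, pj, p, noise = 1.3), c(0, 0, 0))
  pj$pos <- pi_$pos
  expect_error(pairwise_dpd_force(pi_, pj, p), "coincident")
})

test_that("pair force is central and antisymmetric with a shared noise draw", {
  p <- dpd_params()
  set.seed(4)
  for (rep in 1:10) {
    xi <- rnorm(1)
    pi_ <- list(pos = runif(3), vel = rnorm(3), type = "solvent")
    pj <- list(pos = pi_$pos + runif(3, -0.5, 0.5), vel = rnorm(3),
               type = "solvent")
    fij <- pairwise_dpd_force(pi_, pj, p, noise = xi, dt = 0.01)
    fji <- pairwise_dpd_force(pj, pi_, p, noise = xi, dt = 0.01)
    expect_equal(fij + fji, c(0, 0, 0), tolerance = 1e-12)
    rij <- pi_$pos - pj$pos
    crossp <- c(fij[2] * rij[3] - fij[3] * rij[2],
                fij[3] * rij[1] - fij[1] * rij[3],
                fij[1] * rij[2] - fij[2] * rij[1])
    expect_equal(crossp, c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("conservative-only force matches the closed form a * (1 - r/rc)", {
  p <- dpd_params(a = 18.5, gamma = 0)
  r <- p$rc / 2
  pi_ <- list(pos = c(0, 0, 0), vel = c(0, 0, 0), type = "solvent")
  pj <- list(pos = c(r, 0, 0), vel = c(0, 0, 0), type = "solvent")
  f <- pairwise_dpd_force(pi_, pj, p)
  # repulsive: i sits at the origin, j at +x, so i is pushed toward -x
  expect_equal(f, c(-18.5 * (1 - r / p$rc), 0, 0))
})

test_that("neighbour list handles trivial, seam and error cases", {
  box <- list(lo = c(0, 0, 0), hi = c(10, 10, 10),
              periodic = c(TRUE, FALSE, FALSE))
  pos <- rbind(c(1, 5, 5), c(5, 5, 5))
  expect_equal(nrow(build_neighbor_list(pos, 0.5, box)), 0)
  # pair straddling the periodic seam
  pos <- rbind(c(0.1, 5, 5), c(9.9, 5, 5))
  expect_equal(nrow(build_neighbor_list(pos, 0.5, box)), 1)
  expect_error(build_neighbor_list(pos, 6, box), "minimum image")
})

test_that("neighbour list equals the all-pairs oracle on random configurations", {
  for (s in 1:20) {
    box <- list(lo = c(0, 0, 0), hi = c(6, 5, 7),
                periodic = c(TRUE, s %% 2 == 0, FALSE))
    sys <- random_system(60, box, seed = 100 + s)
    nl <- build_neighbor_list(sys, 1, box)
    bf <- brute_pairs(sys$pos, 1, box)
    expect_equal(pair_key(nl), pair_key(bf))
  }
  # denser single case
  box <- list(lo = c(0, 0, 0), hi = c(5, 5, 5), periodic = rep(TRUE, 3))
  sys <- random_system(200, box, seed = 7)
  expect_equal(pair_key(build_neighbor_list(sys, 1.2, box)),
               pair_key(brute_pairs(sys$pos, 1.2, box)))
})

test_that("integrator leaves static systems alone and reproduces the discrete closed form", {
  sys <- particle_system(matrix(runif(9), 3, 3))
  out <- integrate_step(sys, matrix(0, 3, 3), dt = 0.01)
  expect_equal(out$pos, sys$pos)
  # single particle, constant force: x_n = x0 + n dt v0 + n^2 dt^2 f / (2 m)
  f <- c(0.3, -0.2, 0.1)
  s <- particle_system(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3))
  dt <- 0.05
  for (k in 1:20) s <- integrate_step(s, matrix(f, 1, 3), dt)
  n <- 20
  expect_equal(as.numeric(s$pos),
               c(1, 0, 0) * n * dt + n^2 * dt^2 * f / 2,
               tolerance = 1e-12)
  expect_error(integrate_step(s, matrix(c(NaN, 0, 0), 1, 3), dt),
               "particle 1")
})

test_that("wall particles never move and periodic wrap is applied", {
  sys <- particle_system(rbind(c(0.5, 1, 1), c(9.9, 1, 1)),
                         rbind(c(0, 0, 0), c(5, 0, 0)),
                         type = c("wall", "solvent"))
  box <- list(lo = c(0, 0, 0), hi = c(10, 5, 5),
              periodic = c(TRUE, FALSE, FALSE))
  out <- integrate_step(sys, matrix(1, 2, 3), dt = 0.1, box = box)
  expect_equal(out$pos[1, ], c(0.5, 1, 1))
  expect_equal(out$vel[1, ], c(0, 0, 0))
  expect_lt(out$pos[2, 1], 10) # wrapped back into the domain
})

test_that("conservative pair dynamics conserve energy (symplectic integrator)", {
  p <- dpd_params(a = 25, gamma = 0)
  pot <- function(r) if (r >= p$rc) 0 else 0.5 * p$a[1, 1] * p$rc * (1 - r / p$rc)^2
  force_fn <- function(s) {
    d <- s$pos[1, ] - s$pos[2, ]
    r <- sqrt(sum(d^2))
    f1 <- pairwise_dpd_force(list(pos = s$pos[1, ], vel = s$vel[1, ]),
                             list(pos = s$pos[2, ], vel = s$vel[2, ]), p)
    rbind(f1, -f1)
  }
  s <- particle_system(rbind(c(0, 0, 0), c(0.9, 0, 0)),
                       rbind(c(0.2, 0, 0), c(-0.2, 0, 0)))
  etot <- function(s) {
    0.5 * sum(s$vel^2) + pot(sqrt(sum((s$pos[1, ] - s$pos[2, ])^2)))
  }
  e0 <- etot(s)
  for (k in 1:10000) s <- integrate_step(s, force_fn(s), 0.002, force_fn)
  expect_lt(abs(etot(s) - e0) / e0, 1e-4)
})

test_that("kinetic temperature estimator matches a known Maxwell-Boltzmann draw", {
  sys <- particle_system(matrix(0, 1, 3))
  sys$vel <- matrix(0, 1, 3)
  expect_equal(measure_temperature(sys), 0)
  set.seed(11)
  n <- 4000
  s <- particle_system(matrix(runif(3 * n), n, 3),
                       matrix(rnorm(3 * n, 0, 1), n, 3)) # kBT = 1, m = 1
  expect_equal(measure_temperature(s), 1, tolerance = 0.05)
  expect_error(measure_temperature(list()), "empty")
})

test_that("engine force evaluation equals the brute-force all-pairs scan", {
  box <- list(lo = c(0, 0, 0), hi = c(6, 6, 6), periodic = rep(TRUE, 3))
  sys <- random_system(150, box, seed = 21, vel_sd = 0.5)
  inter <- interaction_matrix(dpd_params(), morse_params(enabled = FALSE))
  f_engine <- system_forces(sys, inter, box)
  f_brute <- brute_dpd_forces(sys, inter, box)
  expect_equal(f_engine, f_brute, tolerance = 1e-10)
})

test_that("total momentum is conserved in a periodic unforced box", {
  fx <- make_thermal_box(seed = 2, L = 5, steps = 600)
  r <- run_thermal_box(fx)
  expect_lt(r$momentum_drift, 1e-10)
})
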