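test_that("Morse potential takes its printed values at characteristic separations", {
  p <- morse_params(De = 2, beta = 6, r0 = 0.3, rcut = 2.5)
  # minimum -De at the zero-force distance (tiny continuity shift allowed)
  expect_equal(morse_potential(p$r0, p), -p$De, tolerance = 1e-3)
  # direct substitution r = r0 + ln(2)/beta: De (1/4 - 2 * 1/2) = -0.75 De
  expect_equal(morse_potential(p$r0 + log(2) / p$beta, p), -0.75 * p$De,
               tolerance = 1e-3)
  # exponential decay to zero from below
  vfar <- morse_potential(p$r0 + 6 / p$beta, p)
  expect_lt(vfar, 0)
  expect_gt(vfar, -0.01 * p$De)
  expect_equal(morse_potential(p$rcut + 0.1, p), 0)
  expect_error(morse_potential(-1, p), "positive")
})

test_that("Morse force is zero at r0, repulsive inside, attractive outside", {
  p <- morse_params()
  expect_equal(morse_force(c(p$r0, 0, 0), p), c(0, 0, 0))
  f_in <- morse_force(c(0.9 * p$r0, 0, 0), p)
  expect_gt(f_in[1], 0) # pushes the pair apart
  f_out <- morse_force(c(1.5 * p$r0, 0, 0), p)
  expect_lt(f_out[1], 0) # pulls it back
  expect_equal(morse_force(c(p$rcut * 1.01, 0, 0), p), c(0, 0, 0))
  expect_error(morse_force(c(0, 0, 0), p), "zero-length")
})

test_that("Morse force matches the numeric derivative of the potential", {
  p <- morse_params(De = 1.4, beta = 5, r0 = 0.4, rcut = 3)
  h <- 1e-7
  for (r in seq(0.15, 1.8, by = 0.15)) {
    fnum <- -(morse_potential(r + h, p) - morse_potential(r - h, p)) / (2 * h)
    fana <- morse_force(c(r, 0, 0), p)[1]
    expect_equal(fana, fnum, tolerance = 1e-6 * max(1, abs(fnum)))
  }
})

test_that("distant cells exert no intercellular force; adhesion flag gates the Morse term", {
  m <- build_cell_mesh("sphere", 20, diameter = 1)
  mk_sys <- function(gap) {
    V1 <- m$vertices
    V2 <- sweep(m$vertices, 2, c(gap, 0, 0), "+")
    particle_system(rbind(V1, V2), type = "rbc_membrane",
                    cell = rep(1:2, each = 20))
  }
  box <- list(lo = c(-3, -3, -3), hi = c(9, 3, 3), periodic = rep(FALSE, 3))
  mor <- morse_params(De = 1, beta = 6, r0 = 0.3, rcut = 1.6)
  inter_on <- interaction_matrix(dpd_params(gamma = 0), mor)
  far <- mk_sys(5) # beyond every cutoff
  expect_equal(max(abs(system_forces(far, inter_on, box))), 0)
  # adhesion off reverts to the repulsion-only evaluation
  mor_off <- mor; mor_off$enabled <- FALSE
  inter_off <- interaction_matrix(dpd_params(gamma = 0), mor_off)
  near <- mk_sys(1.1)
  f_off <- system_forces(near, inter_off, box)
  f_rep <- brute_dpd_forces(
    list(pos = near$pos, vel = near$vel, type = rep(0L, 40),
         cell = near$cell),
    list(a = matrix(25, 4, 4), gamma = matrix(0, 4, 4), rc = 1, s = 0.25),
    box)
  expect_equal(f_off, f_rep, tolerance = 1e-10)
  # adhesion on with the surfaces separated by about r0: net attraction of
  # cell 1 toward cell 2 (which sits at +x)
  touching <- mk_sys(1.45)
  f_on <- system_forces(touching, inter_on, box)
  expect_gt(colSums(f_on[1:20, ])[1], 0)
})

test_that("intercellular forces conserve momentum exactly", {
  m <- build_cell_mesh("sphere", 24, diameter = 1.2)
  V2 <- sweep(m$vertices, 2, c(1.0, 0.2, 0), "+")
  sys <- particle_system(rbind(m$vertices, V2), type = "rbc_membrane",
                         cell = rep(1:2, each = 24))
  box <- list(lo = c(-3, -3, -3), hi = c(5, 3, 3), periodic = rep(FALSE, 3))
  inter <- interaction_matrix(dpd_params(), morse_params())
  f <- system_forces(sys, inter, box)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
})

test_that("solvent cannot cross a membrane face when reflection is on, and does when off", {
  m <- build_cell_mesh("sphere", 66, diameter = 2.5)
  nv <- nrow(m$vertices)
  # aim a solvent particle at the centre of the sphere
  sol_pos <- matrix(c(2.2, 0, 0), 1, 3)
  sol_vel <- matrix(c(-2, 0, 0), 1, 3)
  pos <- rbind(sol_pos, m$vertices)
  vel <- rbind(sol_vel, matrix(0, nv, 3))
  run1 <- function(reflect) {
    st <- list(pos = pos, vel = vel, force = matrix(0, nv + 1, 3),
               mass = rep(1, nv + 1), type = c(0L, rep(2L, nv)),
               cell = c(0L, rep(1L, nv)), time = 0,
               rng = c(1, 2, 3, 4), force_stale = TRUE)
    inter <- unclass(interaction_matrix(
      dpd_params(a = 0, gamma = 0), morse_params(enabled = FALSE),
      a_coupling = 0, gamma_coupling = 0, a_membrane = 0))
    inter$sigma <- matrix(0, 4, 4)
    # keep the membrane in place: no bonded forces supplied, so freeze it by
    # leaving membrane velocities zero and applying no interactions
    box <- list(lo = c(-4, -4, -4), hi = c(4, 4, 4),
                periodic = rep(FALSE, 3))
    drv <- list(g = 0, pulse_amp = 0, pulse_period = 0, parent_only = FALSE,
                langevin_gamma = 0, langevin_kbt = 0)
    opts <- list(vmax = 1e3, slab_x0 = 0, slab_x1 = 0, measure = FALSE,
                 reflect_faces = reflect)
    topo <- membrane_topology(m, cell_params("rbc_normal", n_vertices = 66),
                              index_offset = 1L) # solvent occupies row 1
    topo <- mavessel:::topo_zero_terms(topo, character(0))
    out <- mavessel:::cpp_run_chunk(st, unclass(topo), inter, box, NULL,
                                    drv, opts, 600L, 0.005)
    out$pos[1, ]
  }
  p_reflected <- run1(TRUE)
  expect_gt(p_reflected[1], 1.2) # stayed outside the sphere
  p_free <- run1(FALSE)
  expect_lt(p_free[1], -2.2) # negative control: passed straight through
})
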