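mesh66 <- build_cell_mesh("biconcave", 66, volume = 92.5)
pp66 <- cell_params("rbc_normal", n_vertices = 66)
topo66 <- membrane_topology(mesh66, pp66)

test_that("every force term is the exact negative gradient of its energy", {
  V <- perturbed_vertices(mesh66, seed = 3)
  expect_lt(fd_force_error(V, topo66, "elastic"), 1e-4)
  expect_lt(fd_force_error(V, topo66, "bending"), 1e-4)
  expect_lt(fd_force_error(V, topo66, "area"), 1e-4)
  expect_lt(fd_force_error(V, topo66, "volume"), 1e-4)
})

test_that("the built reference state is stress-free for bending, area and volume", {
  r <- total_free_energy(mesh66$vertices, topo66)
  expect_equal(r$vb, 0, tolerance = 1e-9)
  expect_equal(r$va, 0, tolerance = 1e-9)
  expect_equal(r$vv, 0, tolerance = 1e-9)
  expect_gt(r$vs, 0) # WLC + repulsion store energy even at equilibrium
  # per-edge equilibrium: elastic + repulsive forces balance at l0
  el <- elastic_energy_and_forces(mesh66$vertices, topo66)
  expect_lt(max(abs(el$forces)) * mean(mesh66$l0) / r$vs, 1e-10)
})

test_that("total free energy is the sum of its four independently computed terms", {
  V <- perturbed_vertices(mesh66, seed = 9)
  tot <- total_free_energy(V, topo66)
  parts <- c(elastic_energy_and_forces(V, topo66)$vs,
             bending_energy_and_forces(V, topo66)$vb)
  av <- area_volume_energy_and_forces(V, topo66)
  expect_equal(tot$total, sum(parts) + av$va + av$vv, tolerance = 1e-12)
})

test_that("WLC tension rises monotonically and the energy errors at the divergence", {
  cal <- calibrate_wlc_to_shear_modulus(1000, x0 = 0.45, l0 = 0.5)
  fw <- function(x) (1 / cal$p) * (0.25 / (1 - x)^2 - 0.25 + x)
  xs <- seq(0.1, 0.95, by = 0.05)
  expect_true(all(diff(fw(xs)) > 0))
  expect_gt(fw(0.999) / fw(0.9), 100) # divergence approaching l_m
  # stretching one edge to l_m errors, naming the edge
  V <- mesh66$vertices
  e1 <- mesh66$edges[1, ]
  dir <- V[e1[2], ] - V[e1[1], ]
  V[e1[2], ] <- V[e1[1], ] + dir / sqrt(sum(dir^2)) * topo66$lm[1] * 1.01
  expect_error(elastic_energy_and_forces(V, topo66), "maximum extension")
})

test_that("planar patches and angle-matched shapes carry zero bending energy", {
  # regular icosahedron: uniform dihedral angle, theta0 from the built shape
  ico <- build_cell_mesh("sphere", 12, diameter = 1)
  ppi <- cell_params("rbc_normal", n_vertices = 12)
  ti <- membrane_topology(ico, ppi)
  expect_equal(bending_energy_and_forces(ico$vertices, ti)$vb, 0,
               tolerance = 1e-9)
  # flat reference: theta0 = 0 on a sphere gives positive bending energy
  ti0 <- membrane_topology(ico, ppi, theta0 = "flat")
  expect_gt(bending_energy_and_forces(ico$vertices, ti0)$vb, 0)
})

test_that("inflating a sphere produces inward volume-constraint forces", {
  sph <- build_cell_mesh("sphere", 66, diameter = 2)
  pp <- cell_params(NULL, n_vertices = 66, mu0 = 4.73, k0 = 2.4e-19,
                    A0tot = NA, V0tot = unname(sph$volume), shape = "sphere")
  topo <- membrane_topology(sph, pp)
  V <- sph$vertices * 1.1 # inflate about the centroid (origin)
  av <- mavessel:::membrane_eval(V, topo, "volume")
  inward <- rowSums(av$forces * V)
  expect_true(all(inward < 0))
})

test_that("energy decreases monotonically under overdamped relaxation", {
  V <- perturbed_vertices(mesh66, scale = 1.05, sd = 0.03, seed = 5)
  rx <- relax_membrane(V, topo66, steps = 1200, dt = 0.001, damping = 150,
                       sample_every = 200)
  expect_true(all(diff(rx$energy) < 0))
  expect_lt(rx$energy[length(rx$energy)], rx$energy[1])
})

test_that("shear-modulus calibration round-trips the normal and diabetic targets", {
  us <- unit_system()
  l0 <- 0.55
  for (mult in c(1, 5)) {
    mu_model <- mavessel:::mu_to_model(us, 4.73 * mult)
    cal <- calibrate_wlc_to_shear_modulus(mu_model, 0.45, l0)
    back <- wlc_shear_modulus(cal$p, cal$lm, cal$kp, l0)
    expect_equal(back / mu_model, 1, tolerance = 0.005)
  }
  # doubling kBT at fixed geometry doubles the WLC contribution
  cal <- calibrate_wlc_to_shear_modulus(1000, 0.45, l0, kBT = 1)
  mu_wlc_1 <- wlc_shear_modulus(cal$p, cal$lm, 0, l0, kBT = 1)
  mu_wlc_2 <- wlc_shear_modulus(cal$p, cal$lm, 0, l0, kBT = 2)
  expect_equal(mu_wlc_2, 2 * mu_wlc_1)
  expect_error(calibrate_wlc_to_shear_modulus(1000, x0 = 1.2, l0 = 0.5),
               "x0")
})

test_that("presets encode the platelet and diabetic stiffness ratios", {
  rbc <- cell_params("rbc_normal")
  expect_equal(cell_params("platelet")$mu0 / rbc$mu0, 100)
  expect_equal(cell_params("platelet")$k0 / rbc$k0, 100)
  expect_equal(cell_params("rbc_diabetic")$mu0 / rbc$mu0, 5)
  expect_equal(rbc$n_vertices, 500L)
  expect_equal(cell_params("platelet")$n_vertices, 48L)
})

test_that("reduced volume of the printed area/volume pair is 0.64", {
  expect_equal(reduced_volume(132.9, 92.5), 0.642, tolerance = 0.02 / 0.64)
})
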