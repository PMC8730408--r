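#' Validation fixtures
#'
#' Small self-contained scenarios that exercise one physical contract each,
#' at a scale that runs in seconds to minutes on one CPU. Every fixture is
#' generated in code (no external data) and is deterministic per seed.
#'
#' @name fixtures
NULL

#' Quiescent periodic solvent box
#'
#' Pure DPD fluid in a fully periodic cube with no walls or driving;
#' validates the thermostat (measured kinetic temperature within a few
#' percent of the target `kBT`) and exact momentum conservation.
#'
#' @param seed RNG seed
#' @param L box edge, model lengths
#' @param fluid a [dpd_params()]
#' @param steps,dt integration control
#' @return fixture description of class `fixture_config`
#' @export
make_thermal_box <- function(seed = 1, L = 6, fluid = dpd_params(),
                             steps = 4000, dt = 0.01) {
  structure(list(kind = "thermal_box", seed = seed, L = L, fluid = fluid,
                 steps = steps, dt = dt),
            class = "fixture_config")
}

#' @rdname make_thermal_box
#' @param fx a fixture built by [make_thermal_box()]
#' @param sample_after fraction of the run discarded as equilibration
#' @return list: `temperature` (time-averaged, energy units),
#'   `momentum_drift` (max per-particle per-step component drift),
#'   `final_state`
#' @export
run_thermal_box <- function(fx, sample_after = 0.5) {
  p <- fx$fluid
  n <- round(p$density * fx$L^3)
  set.seed(fx$seed)
  pos <- matrix(runif(3 * n, 0, fx$L), n, 3)
  vel <- matrix(rnorm(3 * n, 0, sqrt(p$kBT)), n, 3)
  vel <- sweep(vel, 2, colMeans(vel)) # zero net momentum
  st <- list(pos = pos, vel = vel, force = matrix(0, n, 3),
             mass = rep(1, n), type = rep(0L, n), cell = rep(0L, n),
             time = 0, rng = c(fx$seed, 11, 17, fx$seed + 3),
             force_stale = TRUE)
  inter <- unclass(interaction_matrix(p, morse_params(enabled = FALSE)))
  box <- list(lo = c(0, 0, 0), hi = rep(fx$L, 3),
              periodic = c(TRUE, TRUE, TRUE))
  drv <- list(g = 0, pulse_amp = 0, pulse_period = 0, parent_only = FALSE,
              langevin_gamma = 0, langevin_kbt = 0)
  opts <- list(vmax = 1e3, slab_x0 = 0, slab_x1 = 0, measure = FALSE,
               reflect_faces = FALSE)
  p0 <- colSums(st$vel)
  chunk <- 200L
  temps <- numeric(0)
  done <- 0L
  pdrift <- 0
  while (done < fx$steps) {
    st <- cpp_run_chunk(st, list(), inter, box, NULL, drv, opts, chunk, fx$dt)
    done <- done + chunk
    pdrift <- max(pdrift, max(abs(colSums(st$vel) - p0)))
    if (done > sample_after * fx$steps) {
      temps <- c(temps, sum(st$vel^2) / (3 * n))
    }
  }
  list(temperature = mean(temps),
       momentum_drift = pdrift / (n * fx$steps),
       final_state = st)
}

#' Rectangular-duct Poiseuille validation
#'
#' Straight duct with the parent-channel cross-section (5 x 10 um),
#' body-force driven under the velocity controller; validates no-slip walls
#' and the drive loop. The time-averaged axial velocity profile is compared
#' to the analytic rectangular-duct series solution.
#'
#' @param target_mm_s target mean inlet velocity (mm/s)
#' @param seed RNG seed
#' @param steps run length
#' @param length duct length (model units)
#' @return a [simulation_config()] for a cell-free duct
#' @export
make_poiseuille_slab <- function(target_mm_s = 1.0, seed = 1, steps = 16000,
                                 length = 16) {
  simulation_config(
    geometry = straight_duct(r2 = 5, depth = 10, length = length),
    fluid = dpd_params(),
    morse = morse_params(enabled = FALSE),
    rbc = NULL, platelet = NULL, hematocrit = 0,
    platelet_rate = 0,
    drive = flow_drive(target_mm_s),
    dt = 0.005, steps = steps, output_every = 400, seed = seed,
    store_frames = TRUE)
}

#' Time-averaged axial velocity profile across the duct
#'
#' @param result a [run_simulation()] result with stored frames
#' @param nbins_y,nbins_z bin counts across width and depth
#' @param discard fraction of initial frames dropped as transient
#' @return list with bin centres `y`, `z` and mean-velocity matrix `vx`
#' @export
velocity_profile <- function(result, nbins_y = 10, nbins_z = 10,
                             discard = 0.5) {
  g <- result$config$geometry
  fr <- result$frames
  fr <- fr[seq_along(fr) > discard * length(fr)]
  if (!length(fr)) stop("no frames stored after the discard window")
  sum_v <- matrix(0, nbins_y, nbins_z)
  cnt <- matrix(0, nbins_y, nbins_z)
  for (f in fr) {
    sol <- f$type == 0L
    iy <- pmin(pmax(1L, ceiling(f$pos[sol, 2] / g$r2 * nbins_y)), nbins_y)
    iz <- pmin(pmax(1L, ceiling(f$pos[sol, 3] / g$depth * nbins_z)), nbins_z)
    vx <- f$vel[sol, 1]
    for (k in seq_along(vx)) {
      sum_v[iy[k], iz[k]] <- sum_v[iy[k], iz[k]] + vx[k]
      cnt[iy[k], iz[k]] <- cnt[iy[k], iz[k]] + 1
    }
  }
  list(y = (seq_len(nbins_y) - 0.5) / nbins_y * g$r2,
       z = (seq_len(nbins_z) - 0.5) / nbins_z * g$depth,
       vx = sum_v / pmax(cnt, 1), n = cnt)
}

#' Analytic rectangular-duct flow profile
#'
#' Series solution for pressure-driven laminar flow in a rectangular duct
#' of width `a` (y) and depth `b` (z), normalised to unit mean velocity:
#' \deqn{u(y,z) \propto \sum_{n \,\mathrm{odd}}
#'   \frac{1}{n^3}\left[1 - \frac{\cosh(n\pi(z - b/2)/a)}
#'   {\cosh(n\pi b/(2a))}\right] \sin(n\pi y / a).}
#'
#' @param y,z evaluation coordinates (vectors)
#' @param a,b duct width and depth
#' @param nterms series terms
#' @return matrix `length(y)` x `length(z)` of normalised velocities
#' @export
duct_profile_analytic <- function(y, z, a = 5, b = 10, nterms = 51) {
  u <- matrix(0, length(y), length(z))
  for (n in seq(1, nterms, by = 2)) {
    term <- outer(sin(n * pi * y / a),
                  1 - cosh(n * pi * (z - b / 2) / a) / cosh(n * pi * b / (2 * a)))
    u <- u + term / n^3
  }
  u / mean(u)
}

#' Single-cell stretching fixture
#'
#' Opposing point loads on the outermost vertex groups of a free membrane,
#' the numerical analogue of an optical-tweezers stretch test. Quasi-static
#' loading through damped relaxation at each load step.
#'
#' @param preset cell preset name
#' @param n_vertices mesh resolution
#' @param seed RNG seed (meshes are deterministic; kept for uniformity)
#' @return fixture of class `fixture_config`
#' @export
make_rbc_stretch <- function(preset = "rbc_normal", n_vertices = 162,
                             seed = 1) {
  structure(list(kind = "rbc_stretch", preset = preset,
                 n_vertices = n_vertices, seed = seed),
            class = "fixture_config")
}

#' @rdname make_rbc_stretch
#' @param fx the fixture
#' @param loads total stretching forces (model units), ramped in order
#' @param grip_frac fraction of vertices gripped at each end
#' @param steps relaxation steps per load
#' @return data frame: load, axial and transverse diameters
#' @export
run_rbc_stretch <- function(fx, loads = c(0, 20, 40), grip_frac = 0.05,
                            steps = 3000) {
  pp <- cell_params(fx$preset, n_vertices = fx$n_vertices)
  mesh <- build_cell_mesh(pp$shape, pp$n_vertices, volume = pp$V0tot,
                          aspect_ratio = pp$aspect_ratio)
  topo <- membrane_topology(mesh, pp)
  V <- mesh$vertices
  n <- nrow(V)
  ng <- max(1L, round(grip_frac * n))
  plus <- order(V[, 1], decreasing = TRUE)[seq_len(ng)]
  minus <- order(V[, 1])[seq_len(ng)]
  out <- data.frame()
  for (ld in loads) {
    ext <- matrix(0, n, 3)
    ext[plus, 1] <- ld / ng
    ext[minus, 1] <- -ld / ng
    rx <- relax_membrane(V, topo, steps = steps, dt = 0.002, damping = 2,
                         ext_force = ext)
    V <- rx$vertices
    out <- rbind(out, data.frame(
      load = ld,
      axial = diff(range(V[, 1])),
      transverse = diff(range(V[, 2]))))
  }
  out
}

#' Red-cell adhesion doublet
#'
#' Two red cells at near contact under a Langevin thermostat (quiescent
#' environment): with Morse adhesion on, the doublet persists near the
#' zero-force distance; with adhesion off, thermal diffusion separates the
#' pair.
#'
#' @param adhesion_on logical
#' @param seed RNG seed
#' @param n_vertices mesh resolution per cell
#' @param steps,dt integration control
#' @param morse adhesion parameters
#' @return fixture of class `fixture_config`
#' @export
make_adhesion_doublet <- function(adhesion_on = TRUE, seed = 1,
                                  n_vertices = 66, steps = 6000, dt = 0.004,
                                  morse = morse_params()) {
  morse$enabled <- adhesion_on
  structure(list(kind = "adhesion_doublet", adhesion_on = adhesion_on,
                 seed = seed, n_vertices = n_vertices, steps = steps,
                 dt = dt, morse = morse),
            class = "fixture_config")
}

#' @rdname make_adhesion_doublet
#' @param fx the fixture
#' @return list: `closest` (trajectory of closest vertex-pair distance),
#'   `separation0`, `separation1` (initial/final centre distances)
#' @export
run_adhesion_doublet <- function(fx) {
  pp <- cell_params("rbc_normal", n_vertices = fx$n_vertices)
  mesh <- build_cell_mesh(pp$shape, pp$n_vertices, volume = pp$V0tot)
  V1 <- mesh$vertices
  thick <- diff(range(V1[, 3]))
  V2 <- V1
  V2[, 3] <- V2[, 3] + thick + fx$morse$r0 # face-to-face, near contact
  m1 <- mesh; m2 <- mesh
  m1$vertices <- V1
  m2$vertices <- V2
  topo <- membrane_topology(list(m1, m2), pp)
  n1 <- nrow(V1)
  pos <- rbind(V1, V2)
  n <- nrow(pos)
  st <- list(pos = pos, vel = matrix(0, n, 3), force = matrix(0, n, 3),
             mass = rep(1, n), type = rep(2L, n),
             cell = rep(1:2, each = n1), time = 0,
             rng = c(fx$seed, 5, 9, fx$seed + 1), force_stale = TRUE)
  inter <- unclass(interaction_matrix(dpd_params(), fx$morse))
  pad <- 8
  lo <- apply(pos, 2, min) - pad
  hi <- apply(pos, 2, max) + pad
  box <- list(lo = lo, hi = hi, periodic = c(FALSE, FALSE, FALSE))
  drv <- list(g = 0, pulse_amp = 0, pulse_period = 0, parent_only = FALSE,
              langevin_gamma = 1, langevin_kbt = 1)
  opts <- list(vmax = 1e3, slab_x0 = 0, slab_x1 = 0, measure = FALSE,
               reflect_faces = FALSE)
  closest <- function(p) {
    a <- p[seq_len(n1), ]
    b <- p[n1 + seq_len(n1), ]
    min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
               outer(a[, 3], b[, 3], "-")^2))
  }
  sep <- function(p) {
    sqrt(sum((colMeans(p[seq_len(n1), ]) - colMeans(p[n1 + seq_len(n1), ]))^2))
  }
  s0 <- sep(pos)
  chunk <- 300L
  done <- 0L
  cl <- numeric(0)
  while (done < fx$steps) {
    st <- cpp_run_chunk(st, unclass(topo), inter, box, NULL, drv, opts,
                        chunk, fx$dt)
    if (st$diag$unstable) stop("doublet fixture unstable")
    done <- done + chunk
    cl <- c(cl, closest(st$pos))
  }
  list(closest = cl, separation0 = s0, separation1 = sep(st$pos))
}

#' Desk-scale microaneurysm scenario
#'
#' The full channel protocol at true geometric dimensions but reduced
#' solvent density, coarser cell meshes and a short run -- sized so trends
#' (orderings across conditions), not absolute magnitudes, are the
#' comparable output.
#'
#' @param bnr body-to-neck ratio (2.2, 3, 5.4 or 8)
#' @param hematocrit red-cell volume fraction (0.1, 0.2 or 0.4)
#' @param velocity_mm_s target inlet velocity
#' @param adhesion enable red-cell adhesion
#' @param stiff use the 5x-stiff diabetic red-cell preset
#' @param pulsatile pulsatile driving
#' @param rbc_placement `"lumen"` fills the whole channel (the protocol all
#'   hematocrit levels share in the transport comparisons); `"parent"`
#'   seeds the parent vessel only (the perfusion-study protocol)
#' @param seed RNG seed
#' @param steps run length
#' @return a [simulation_config()]
#' @export
make_mini_ma <- function(bnr, hematocrit = 0.4, velocity_mm_s = 1.5,
                         adhesion = FALSE, stiff = FALSE, pulsatile = FALSE,
                         rbc_placement = c("lumen", "parent"),
                         seed = 1, steps = 6400) {
  rbc_placement <- match.arg(rbc_placement)
  stopifnot(bnr %in% c(2.2, 3, 5.4, 8))
  rbc_preset <- if (stiff) "rbc_diabetic" else "rbc_normal"
  drv <- if (pulsatile) flow_drive(velocity_mm_s, "pulsatile")
         else flow_drive(velocity_mm_s)
  # desk-scale platelet: 3x the red-cell moduli (stiff relative to the red
  # cells at these stresses) and a moderately heavier vertex -- the lightest
  # combination whose bond frequencies stay inside the stability limit of
  # the coarse time step. Excess vertex mass suppresses the collision-driven
  # lateral motion that carries platelets into the aneurysm, so mass is kept
  # as low as stability allows; the shipped 100x preset is exercised at a
  # finer step in its own fixture.
  plt <- cell_params("platelet")
  plt$mu0 <- 3 * 4.73
  plt$k0 <- 3 * 2.4e-19
  plt$vertex_mass <- 4
  # coarse-mesh adhesion kernel: short-ranged so the Morse cutoff matches
  # the fluid cutoff (no widened neighbour stencil), with the per-pair well
  # depth scaled up by the vertex-area ratio (l0_coarse/l0_fine)^2 ~ 7 so
  # the adhesion energy per unit membrane area matches a fine-mesh well of
  # a few kBT; the doublet fixture validates aggregation at rest
  mor <- morse_params(De = 25, beta = 10, r0 = 0.2, rcut = 1,
                      enabled = adhesion)
  simulation_config(
    geometry = build_ma_channel(bnr, length = max(bnr * 5 + 17, 36)),
    fluid = dpd_params(density = 1),
    morse = mor,
    rbc = cell_params(rbc_preset, n_vertices = 66L, vertex_mass = 3),
    platelet = plt,
    hematocrit = hematocrit,
    rbc_placement = rbc_placement,
    platelet_rate = 1000,
    drive = drv, dt = 0.008, steps = steps, output_every = 160,
    seed = seed, wall_density = 1.5)
}
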