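#' Cell membrane model parameters
#'
#' Macroscopic mechanical targets and penalty coefficients for one cell
#' preset. Three presets are shipped:
#' \describe{
#'   \item{rbc_normal}{biconcave disc, 500 vertices, shear modulus
#'     `mu0` = 4.73 uN/m, bending rigidity `k0` = 2.4e-19 J, reference area
#'     132.9 um^2 and volume 92.5 um^3 (surface-to-volume ratio 1.44).}
#'   \item{rbc_diabetic}{as `rbc_normal` with the shear modulus increased
#'     5-fold, the stiffening reported for diabetic red cells.}
#'   \item{platelet}{oblate spheroid, 48 vertices, aspect ratio 0.38,
#'     volume 6 um^3; shear and bending moduli 100x the normal red cell so
#'     the particle behaves as a rigid body in its passive state.}
#' }
#'
#' @param preset preset name, or `NULL` to set every field explicitly
#' @param n_vertices membrane vertex count
#' @param mu0 membrane shear modulus, uN/m
#' @param k0 bending rigidity, J
#' @param A0tot reference surface area, um^2 (`NA`: use the built mesh area)
#' @param V0tot reference volume, um^3
#' @param ka,kv,kd global-area, volume and local-area penalty coefficients
#'   (model energy units); defaults hold area and volume within 1 percent
#' @param x0 worm-like-chain extension ratio l0/lm at the reference state
#' @param pow_m exponent of the power-law bond repulsion
#' @param shape mesh shape family
#' @param aspect_ratio thickness/diameter for the oblate family
#' @param vertex_mass mass per membrane vertex (model units); the platelet
#'   preset uses a heavier vertex so its 100x-stiffer bonds remain stable at
#'   the coarse time steps of desk-scale runs (rigid-body behaviour is
#'   unaffected)
#' @return object of class `cell_params`
#' @examples
#' cell_params("platelet")$mu0 / cell_params("rbc_normal")$mu0 # 100
#' @export
cell_params <- function(preset = c("rbc_normal", "rbc_diabetic", "platelet"),
                        n_vertices = NULL, mu0 = NULL, k0 = NULL,
                        A0tot = NULL, V0tot = NULL,
                        ka = 5000, kv = 5000, kd = 100,
                        x0 = 0.45, pow_m = 2,
                        shape = NULL, aspect_ratio = 0.38,
                        vertex_mass = NULL) {
  base <- list(
    rbc_normal = list(n_vertices = 500L, mu0 = 4.73, k0 = 2.4e-19,
                      A0tot = 132.9, V0tot = 92.5, shape = "biconcave"),
    rbc_diabetic = list(n_vertices = 500L, mu0 = 5 * 4.73, k0 = 2.4e-19,
                        A0tot = 132.9, V0tot = 92.5, shape = "biconcave"),
    platelet = list(n_vertices = 48L, mu0 = 100 * 4.73, k0 = 100 * 2.4e-19,
                    A0tot = NA_real_, V0tot = 6, shape = "oblate",
                    vertex_mass = 6)
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    b <- base[[preset]]
  } else {
    preset <- "custom"
    b <- list()
  }
  p <- list(
    preset = preset,
    n_vertices = as.integer(n_vertices %||% b$n_vertices),
    mu0 = mu0 %||% b$mu0,
    k0 = k0 %||% b$k0,
    A0tot = A0tot %||% b$A0tot,
    V0tot = V0tot %||% b$V0tot,
    ka = ka, kv = kv, kd = kd, x0 = x0, pow_m = pow_m,
    shape = shape %||% b$shape,
    aspect_ratio = aspect_ratio,
    vertex_mass = vertex_mass %||% b$vertex_mass %||% 1
  )
  stopifnot(p$mu0 > 0, p$k0 > 0, p$V0tot > 0, p$x0 > 0, p$x0 < 1)
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params> %s: Nv=%d mu0=%g uN/m k0=%g J A0=%g um^2 V0=%g um^3\n",
    x$preset, x$n_vertices, x$mu0, x$k0, x$A0tot, x$V0tot))
  invisible(x)
}

# WLC tension factor f(x0) = 1/(4(1-x)^2) - 1/4 + x (times kBT/p) and the
# shear-modulus bracket of the WLC + power-repulsion network
wlc_c0 <- function(x0) 0.25 / (1 - x0)^2 - 0.25 + x0
wlc_c1 <- function(x0) x0 / (2 * (1 - x0)^3) - 0.25 / (1 - x0)^2 + 0.25

#' Small-strain shear modulus of a WLC + power-repulsion network
#'
#' Closed-form linear shear modulus of a regular triangulated network whose
#' edges carry a worm-like-chain attraction (persistence length `p`, maximum
#' extension `lm`) balanced by a power-law repulsion `kp / l^m`:
#' \deqn{\mu_0 = \frac{\sqrt3 k_BT}{4 p l_m x_0}\left(
#'   \frac{x_0}{2(1-x_0)^3} - \frac{1}{4(1-x_0)^2} + \frac14\right)
#'   + \frac{\sqrt3 (m+1) k_p}{4 l_0^{m+1}}, \qquad x_0 = l_0 / l_m.}
#'
#' @param p WLC persistence length (model length units)
#' @param lm maximum bond extension
#' @param kp power-law repulsion coefficient
#' @param l0 equilibrium bond length
#' @param kBT thermal energy (model units)
#' @param m repulsion exponent
#' @return shear modulus in model units (energy / length^2)
#' @export
wlc_shear_modulus <- function(p, lm, kp, l0, kBT = 1, m = 2) {
  x0 <- l0 / lm
  sqrt(3) * kBT / (4 * p * lm * x0) * wlc_c1(x0) +
    sqrt(3) * (m + 1) * kp / (4 * l0^(m + 1))
}

#' Calibrate membrane bond coefficients to a target shear modulus
#'
#' Solves the closed-form network relation of [wlc_shear_modulus()] for the
#' WLC persistence length, with the repulsion coefficient fixed by the
#' per-bond equilibrium condition (WLC attraction equals power-law repulsion
#' at the reference length `l0`). The returned coefficients reproduce the
#' target modulus through the closed form to machine precision.
#'
#' @param target_mu0 target shear modulus, model units (energy / length^2)
#' @param x0 extension ratio l0/lm (0 < x0 < 1)
#' @param l0 equilibrium bond length, model length units
#' @param kBT thermal energy
#' @param m repulsion exponent
#' @return list with `p`, `lm`, `kp`, `kwlc` (= kBT/p) and the echoed inputs
#' @examples
#' us <- unit_system()
#' mu_model <- 4.73e-6 * (us$length_scale * 1e-6)^2 / us$energy_scale
#' cal <- calibrate_wlc_to_shear_modulus(mu_model, 0.45, 0.55)
#' wlc_shear_modulus(cal$p, cal$lm, cal$kp, 0.55) / mu_model # 1
#' @export
calibrate_wlc_to_shear_modulus <- function(target_mu0, x0, l0, kBT = 1,
                                           m = 2) {
  if (!(x0 > 0 && x0 < 1)) stop("x0 must lie strictly inside (0, 1)")
  stopifnot(target_mu0 > 0, l0 > 0)
  bracket <- wlc_c1(x0) + (m + 1) * wlc_c0(x0)
  p <- sqrt(3) * kBT * bracket / (4 * l0 * target_mu0)
  kp <- (kBT / p) * wlc_c0(x0) * l0^m
  list(p = p, lm = l0 / x0, kp = kp, kwlc = kBT / p,
       x0 = x0, l0 = l0, kBT = kBT, m = m)
}

#' Convert physical membrane moduli to model units
#' @param us a [unit_system()]
#' @param mu_uN_per_m shear modulus in uN/m
#' @return model-unit value (energy / length^2)
#' @keywords internal
mu_to_model <- function(us, mu_uN_per_m) {
  mu_uN_per_m * 1e-6 * (us$length_scale * 1e-6)^2 / us$energy_scale
}

k0_to_model <- function(us, k0_J) k0_J / us$energy_scale

#' Assemble the bonded-force description of one or more membranes
#'
#' Builds the per-edge WLC/repulsion coefficients (calibrated to the
#' preset's shear modulus, with each edge in equilibrium at its own built
#' length), the per-dihedral bending stiffness
#' \eqn{k_b = 2 k_0 / \sqrt 3} with the built shape as spontaneous-angle
#' reference, and the per-cell area/volume constraint targets.
#'
#' @param meshes list of `triangulated_membrane` (one per cell)
#' @param params list of [cell_params()] (recycled if length 1)
#' @param us a [unit_system()] fixing the model units
#' @param index_offset 0-based offsets of each cell's vertices in the global
#'   particle arrays (default: cells concatenated from 1)
#' @param theta0 `"reference"` (built shape, stress-free) or `"flat"` (0)
#' @return a `membrane_topology` list consumed by the engine
#' @export
membrane_topology <- function(meshes, params, us = unit_system(),
                              index_offset = NULL, theta0 = "reference") {
  if (inherits(meshes, "triangulated_membrane")) meshes <- list(meshes)
  if (inherits(params, "cell_params")) params <- list(params)
  params <- rep_len(params, length(meshes))
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  if (is.null(index_offset)) index_offset <- cumsum(c(0L, head(nv, -1)))

  edges <- NULL; l0 <- lm <- kp <- kwlc <- numeric(0)
  dihedrals <- NULL; th0 <- kb <- numeric(0)
  faces <- NULL; face_cell <- integer(0); at0 <- numeric(0)
  A0 <- V0 <- ka <- kv <- kd <- numeric(0)

  for (ci in seq_along(meshes)) {
    m <- meshes[[ci]]; pp <- params[[ci]]; off <- index_offset[ci]
    mu_model <- mu_to_model(us, pp$mu0)
    el0 <- m$l0
    cal <- calibrate_wlc_to_shear_modulus(mu_model, pp$x0, mean(el0),
                                          kBT = 1, m = pp$pow_m)
    edges <- rbind(edges, m$edges + off)
    l0 <- c(l0, el0)
    lm <- c(lm, el0 / pp$x0)
    kp <- c(kp, (1 / cal$p) * wlc_c0(pp$x0) * el0^pp$pow_m)
    kwlc <- c(kwlc, rep(1 / cal$p, length(el0)))
    dihedrals <- rbind(dihedrals, m$dihedrals + off)
    nd <- nrow(m$dihedrals)
    th0 <- c(th0, if (identical(theta0, "flat")) rep(0, nd) else m$theta0)
    kb <- c(kb, rep(2 * k0_to_model(us, pp$k0) / sqrt(3), nd))
    faces <- rbind(faces, m$faces + off)
    face_cell <- c(face_cell, rep(ci, nrow(m$faces)))
    V <- m$vertices
    tri_a <- sqrt(rowSums(t(apply(m$faces, 1, function(f) {
      cross3(V[f[2], ] - V[f[1], ], V[f[3], ] - V[f[1], ])
    }))^2)) / 2
    at0 <- c(at0, tri_a)
    # constraint references are the built mesh's own area/volume: the preset
    # targets pin the construction (volume exactly, area through the shape
    # family), but the discrete reference state must be attainable at any
    # mesh resolution
    A0 <- c(A0, sum(tri_a))
    V0 <- c(V0, unname(m$volume))
    ka <- c(ka, pp$ka); kv <- c(kv, pp$kv); kd <- c(kd, pp$kd)
  }
  structure(
    list(edges = edges, l0 = l0, lm = lm, kp = kp, kwlc = kwlc,
         pow_m = params[[1]]$pow_m,
         dihedrals = dihedrals, theta0 = th0, kb = kb,
         faces = faces, face_cell = face_cell, at0 = at0,
         A0 = A0, V0 = V0, ka = ka, kv = kv, kd = kd),
    class = "membrane_topology"
  )
}

topo_zero_terms <- function(topo, keep) {
  if (!("elastic" %in% keep)) {
    topo$kwlc[] <- 0
    topo$kp[] <- 0
  }
  if (!("bending" %in% keep)) topo$kb[] <- 0
  if (!("area" %in% keep)) {
    topo$ka[] <- 0
    topo$kd[] <- 0
  }
  if (!("volume" %in% keep)) topo$kv[] <- 0
  topo
}

membrane_eval <- function(vertices, topo, keep, want_forces = TRUE) {
  res <- cpp_membrane_forces(as.matrix(vertices), topo_zero_terms(topo, keep),
                             want_forces)
  res
}

#' Membrane energy terms and forces
#'
#' `elastic_energy_and_forces`, `bending_energy_and_forces` and
#' `area_volume_energy_and_forces` evaluate individual terms of the membrane
#' free energy and their exact negative gradients;
#' `total_free_energy` reports the full sum with a per-term breakdown.
#'
#' @param vertices n x 3 vertex positions (may differ from the reference
#'   state stored in the topology)
#' @param topo a [membrane_topology()]
#' @return list with the energy term(s) and an n x 3 `forces` matrix
#' @export
elastic_energy_and_forces <- function(vertices, topo) {
  r <- membrane_eval(vertices, topo, "elastic")
  list(vs = r$vs, forces = r$forces)
}

#' @rdname elastic_energy_and_forces
#' @export
bending_energy_and_forces <- function(vertices, topo) {
  r <- membrane_eval(vertices, topo, "bending")
  list(vb = r$vb, forces = r$forces)
}

#' @rdname elastic_energy_and_forces
#' @export
area_volume_energy_and_forces <- function(vertices, topo) {
  r <- membrane_eval(vertices, topo, c("area", "volume"))
  list(va = r$va, vv = r$vv, forces = r$forces)
}

#' @rdname elastic_energy_and_forces
#' @export
total_free_energy <- function(vertices, topo) {
  r <- membrane_eval(vertices, topo, c("elastic", "bending", "area", "volume"),
                     want_forces = FALSE)
  list(total = r$vs + r$vb + r$va + r$vv,
       vs = r$vs, vb = r$vb, va = r$va, vv = r$vv)
}

#' Damped relaxation of membrane vertices
#'
#' Overdamped descent on the total membrane free energy (Langevin dynamics
#' at zero temperature), used to settle freshly built meshes and as the
#' quasi-static integrator of the stretching fixture.
#'
#' @param vertices n x 3 starting positions
#' @param topo a [membrane_topology()]
#' @param steps,dt integration steps and time step
#' @param damping friction coefficient
#' @param ext_force optional n x 3 static external force
#' @param kBT thermostat temperature for the Langevin bath (0 = pure
#'   damping, i.e. energy descent; > 0 samples thermal membrane motion)
#' @return list with final `vertices` and the trajectory of total energy
#'   sampled every `sample_every` steps
#' @param sample_every energy sampling cadence
#' @export
relax_membrane <- function(vertices, topo, steps = 2000, dt = 0.002,
                           damping = 2, ext_force = NULL,
                           sample_every = 100, kBT = 0) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  pad <- 8
  lo <- apply(vertices, 2, min) - pad
  hi <- apply(vertices, 2, max) + pad
  st <- list(pos = vertices, vel = matrix(0, n, 3),
             force = matrix(0, n, 3), mass = rep(1, n),
             type = rep(2L, n), cell = rep(1L, n),
             time = 0, rng = c(1, 2, 3, 4), force_stale = TRUE)
  inter <- list(a = matrix(0, 4, 4), gamma = matrix(0, 4, 4),
                sigma = matrix(0, 4, 4), rc = 1, s = 0.25,
                morse_on = FALSE, morse_de = 0, morse_beta = 1,
                morse_r0 = 1, morse_rcut = 1)
  box <- list(lo = lo, hi = hi, periodic = c(FALSE, FALSE, FALSE))
  drv <- list(g = 0, pulse_amp = 0, pulse_period = 0, parent_only = FALSE,
              ext_force = ext_force, langevin_gamma = damping,
              langevin_kbt = kBT)
  opts <- list(vmax = 1e4, slab_x0 = 0, slab_x1 = 0, measure = FALSE,
               reflect_faces = FALSE)
  energies <- numeric(0)
  areas <- numeric(0)
  volumes <- numeric(0)
  done <- 0
  while (done < steps) {
    k <- min(sample_every, steps - done)
    st <- cpp_run_chunk(st, unclass(topo), inter, box, NULL, drv, opts, k, dt)
    if (st$diag$unstable) {
      stop("membrane relaxation unstable: ",
           if (nzchar(st$diag$mem_err)) st$diag$mem_err else "velocity blow-up")
    }
    done <- done + k
    energies <- c(energies, total_free_energy(st$pos, topo)$total)
    av <- mesh_area_volume(list(vertices = st$pos, faces = topo$faces))
    areas <- c(areas, av["area"])
    volumes <- c(volumes, av["volume"])
  }
  list(vertices = st$pos, energy = energies, area = areas, volume = volumes)
}
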