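#' Morse potential parameters for red-cell adhesion
#'
#' Fibrinogen-mediated attraction between membrane vertices of distinct red
#' blood cells is modelled with the Morse potential
#' \deqn{V_M(r) = D_e\left[e^{2\beta(r_0 - r)} - 2 e^{\beta(r_0 - r)}\right]}
#' whose minimum is \eqn{-D_e} at the zero-force distance \eqn{r_0}. All
#' membrane vertices are treated as adhesive (the high-fibrinogen limit);
#' `adhesive_fraction` is retained as a parameter for concentration-dependent
#' studies. The default constants give a short-ranged well (decay length
#' 1/beta) whose tail is negligible (< 1e-3 De) at the cutoff.
#'
#' @param De well depth, model energy units
#' @param beta inverse interaction range, 1/length
#' @param r0 zero-force distance, model length units
#' @param rcut interaction cutoff
#' @param enabled logical: apply adhesion between distinct red cells
#' @param adhesive_fraction fraction of adhesive membrane vertices
#' @return object of class `morse_params`
#' @examples
#' p <- morse_params()
#' morse_potential(p$r0, p) # approximately -De
#' @export
morse_params <- function(De = 1, beta = 6, r0 = 0.3, rcut = 1.6,
                         enabled = TRUE, adhesive_fraction = 1) {
  stopifnot(De > 0, beta > 0, r0 > 0, rcut > r0)
  tail <- abs(exp(2 * beta * (r0 - rcut)) - 2 * exp(beta * (r0 - rcut)))
  if (tail > 1e-3) {
    warning(sprintf(
      "Morse tail |V(rcut)|/De = %.2g exceeds 1e-3; consider a larger rcut",
      tail))
  }
  structure(
    list(De = De, beta = beta, r0 = r0, rcut = rcut, enabled = enabled,
         adhesive_fraction = adhesive_fraction),
    class = "morse_params"
  )
}

#' Morse pair potential and force
#'
#' Exact evaluation of the Morse interaction, shifted by its (negligible)
#' cutoff value so the potential is continuous at `rcut` and zero beyond.
#' The force is the analytic derivative: repulsive below the zero-force
#' distance `r0`, attractive between `r0` and `rcut`.
#'
#' @param r separation distance(s), > 0
#' @param p a [morse_params()]
#' @return `morse_potential`: energy; `morse_force`: 3-vector force on the
#'   first particle of the pair
#' @export
morse_potential <- function(r, p) {
  if (any(r <= 0)) stop("separation must be positive")
  eb <- exp(p$beta * (p$r0 - r))
  v <- p$De * (eb^2 - 2 * eb)
  ebc <- exp(p$beta * (p$r0 - p$rcut))
  vcut <- p$De * (ebc^2 - 2 * ebc)
  ifelse(r < p$rcut, v - vcut, 0)
}

#' @rdname morse_potential
#' @param r_vec separation 3-vector (first particle minus second)
#' @export
morse_force <- function(r_vec, p) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("zero-length separation vector")
  if (r >= p$rcut) return(c(0, 0, 0))
  eb <- exp(p$beta * (p$r0 - r))
  fmag <- 2 * p$beta * p$De * (eb^2 - eb) # -dV/dr, >0 repulsive
  fmag * r_vec / r
}

#' Interaction matrix across particle types
#'
#' Assembles the per-type-pair DPD coefficients and the Morse adhesion
#' switch consumed by the engine. Conventions:
#' \itemize{
#'   \item solvent--solvent, solvent--wall, wall--membrane and
#'     platelet-involved membrane pairs: plain DPD with the fluid
#'     coefficients (conservative amplitude `a_fluid`);
#'   \item solvent--membrane: reduced conservative amplitude and elevated
#'     friction (`gamma_coupling`) so the fluid satisfies no-slip on the
#'     moving membrane, complementing face reflection;
#'   \item red-cell--red-cell (distinct cells): when adhesion is enabled the
#'     Morse potential supplies both the short-range repulsive core and the
#'     attractive well and the conservative DPD amplitude is dropped;
#'     with adhesion disabled the pair reverts to plain repulsive DPD.
#' }
#' Dissipative/random pairs always satisfy sigma^2 = 2 gamma kBT.
#'
#' @param fluid a [dpd_params()]
#' @param morse a [morse_params()]
#' @param a_coupling conservative amplitude solvent--membrane
#' @param gamma_coupling dissipative coefficient solvent--membrane
#' @param a_membrane conservative amplitude between membranes of distinct
#'   cells (and membrane--wall)
#' @return list of engine coefficient matrices (class `interaction_matrix`)
#' @export
interaction_matrix <- function(fluid = dpd_params(),
                               morse = morse_params(),
                               a_coupling = 10,
                               gamma_coupling = 20,
                               a_membrane = 25) {
  a <- fluid$a
  g <- fluid$gamma
  # indices: 1 solvent, 2 wall, 3 rbc, 4 platelet
  for (m in 3:4) {
    a[1, m] <- a[m, 1] <- a_coupling
    g[1, m] <- g[m, 1] <- gamma_coupling
    a[2, m] <- a[m, 2] <- a_membrane
  }
  a[3, 4] <- a[4, 3] <- a_membrane
  a[4, 4] <- a_membrane
  a[3, 3] <- if (morse$enabled) 0 else a_membrane
  structure(
    list(a = a, gamma = g, sigma = sqrt(2 * g * fluid$kBT),
         rc = fluid$rc, s = fluid$s,
         morse_on = morse$enabled, morse_de = morse$De,
         morse_beta = morse$beta, morse_r0 = morse$r0,
         morse_rcut = morse$rcut, kBT = fluid$kBT),
    class = "interaction_matrix"
  )
}

#' Evaluate total nonbonded + bonded forces of a configuration
#'
#' Single force evaluation through the engine (no time stepping): DPD pair
#' forces via the cell-list neighbour search, Morse adhesion across distinct
#' red cells, and membrane bonded forces when a topology is supplied. With
#' the random amplitude zeroed this is deterministic and comparable to a
#' brute-force all-pairs evaluation.
#'
#' @param system a [particle_system()]
#' @param inter an [interaction_matrix()]
#' @param box box list (`lo`, `hi`, `periodic`)
#' @param topo optional [membrane_topology()]
#' @param zero_noise drop the random force term (deterministic output)
#' @return n x 3 matrix of forces
#' @export
system_forces <- function(system, inter, box, topo = NULL,
                          zero_noise = TRUE) {
  inter2 <- unclass(inter)
  if (zero_noise) inter2$sigma <- matrix(0, 4, 4)
  n <- nrow(system$pos)
  st <- list(pos = system$pos, vel = system$vel,
             force = matrix(0, n, 3), mass = system$mass,
             type = system$type, cell = system$cell,
             time = 0, rng = c(1, 2, 3, 4), force_stale = TRUE)
  drv <- list(g = 0, pulse_amp = 0, pulse_period = 0, parent_only = FALSE,
              langevin_gamma = 0, langevin_kbt = 0)
  opts <- list(vmax = Inf, slab_x0 = 0, slab_x1 = 0, measure = FALSE,
               reflect_faces = FALSE)
  out <- cpp_run_chunk(st, if (is.null(topo)) list() else unclass(topo),
                       inter2, box, NULL, drv, opts, 0L, 0.01)
  out$force
}
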