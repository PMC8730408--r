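#' Particle types used throughout the engine
#'
#' Integer codes: solvent = 0, wall = 1, rbc_membrane = 2,
#' platelet_membrane = 3.
#' @keywords internal
PARTICLE_TYPES <- c(solvent = 0L, wall = 1L,
                    rbc_membrane = 2L, platelet_membrane = 3L)

as_type_code <- function(type) {
  if (is.character(type)) {
    code <- PARTICLE_TYPES[type]
    if (anyNA(code)) stop("unknown particle type: ", type[is.na(code)][1])
    unname(code)
  } else {
    as.integer(type)
  }
}

#' DPD fluid parameters
#'
#' Pairwise-force coefficients of the dissipative particle dynamics fluid.
#' The conservative, dissipative and random forces use
#' \deqn{F^C = a_{ij}(1 - r/r_c)\hat r, \quad
#'       F^D = -\gamma w_R(r)^2 (\hat r \cdot v_{ij})\hat r, \quad
#'       F^R = \sigma w_R(r)\, \theta_{ij} \, \hat r / \sqrt{dt},}
#' with \eqn{w_R(r) = (1 - r/r_c)^s} and \eqn{\sigma^2 = 2\gamma k_BT}
#' enforced by construction (fluctuation--dissipation). The exponent `s < 1`
#' raises the fluid viscosity at fixed `gamma`, a common choice for
#' cell-suspension DPD.
#'
#' `a` and `gamma` may be scalars (all type pairs identical) or symmetric
#' 4x4 matrices indexed by the particle type codes
#' (solvent, wall, rbc_membrane, platelet_membrane).
#'
#' @param a conservative amplitude(s)
#' @param gamma dissipative coefficient(s)
#' @param kBT target temperature in model energy units
#' @param rc cutoff radius
#' @param s random-force weight exponent
#' @param density solvent number density (particles per cubic model length)
#' @return object of class `dpd_params`
#' @examples
#' p <- dpd_params()
#' p$sigma[1, 1]^2 / (2 * p$gamma[1, 1]) # equals kBT
#' @export
dpd_params <- function(a = 25, gamma = 4.5, kBT = 1, rc = 1, s = 0.25,
                       density = 3) {
  stopifnot(rc > 0, kBT > 0, s > 0, density > 0)
  expand <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, 4, 4)
    x <- as.matrix(x)
    if (!all(dim(x) == c(4, 4))) stop(what, " must be scalar or 4x4")
    if (any(x < 0)) stop(what, " coefficients must be >= 0")
    if (!isTRUE(all.equal(x, t(x)))) stop(what, " matrix must be symmetric")
    x
  }
  a <- expand(a, "a")
  gamma <- expand(gamma, "gamma")
  structure(
    list(a = a, gamma = gamma, sigma = sqrt(2 * gamma * kBT),
         kBT = kBT, rc = rc, s = s, density = density),
    class = "dpd_params"
  )
}

#' @export
print.dpd_params <- function(x, ...) {
  cat(sprintf(
    "<dpd_params> a_ss=%g gamma_ss=%g kBT=%g rc=%g s=%g density=%g\n",
    x$a[1, 1], x$gamma[1, 1], x$kBT, x$rc, x$s, x$density))
  invisible(x)
}

#' Container for particle state
#'
#' Positions, velocities, type codes, masses and owning-cell ids of all
#' particles (solvent, frozen wall, membrane vertices).
#'
#' @param pos n x 3 matrix of positions (model length units)
#' @param vel n x 3 matrix of velocities
#' @param type particle types (names or integer codes)
#' @param mass per-particle masses (recycled)
#' @param cell owning cell id per particle (0 = none)
#' @return object of class `particle_system`
#' @export
particle_system <- function(pos, vel = NULL, type = "solvent", mass = 1,
                            cell = 0L) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3) stop("pos must be an n x 3 matrix")
  n <- nrow(pos)
  if (!all(is.finite(pos))) stop("non-finite coordinates")
  if (is.null(vel)) vel <- matrix(0, n, 3)
  vel <- as.matrix(vel)
  type <- rep_len(as_type_code(type), n)
  mass <- rep_len(as.numeric(mass), n)
  cell <- rep_len(as.integer(cell), n)
  if (any(type == PARTICLE_TYPES["wall"] &
          rowSums(abs(vel)) > 0)) {
    stop("wall particles must have zero velocity")
  }
  structure(
    list(pos = pos, vel = vel, type = type, mass = mass, cell = cell),
    class = "particle_system"
  )
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(factor(x$type, levels = PARTICLE_TYPES,
                      labels = names(PARTICLE_TYPES)))
  cat(sprintf("<particle_system> %d particles (%s)\n", nrow(x$pos),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Pairwise DPD force between two particles
#'
#' Reference (scalar-pair) evaluation of the conservative + dissipative +
#' random DPD force triplet on particle `i`, central along the separation
#' vector and antisymmetric under exchange when the same `noise` draw is
#' shared. Zero beyond the cutoff.
#'
#' @param p_i,p_j particle states: lists with `pos`, `vel` (3-vectors) and
#'   `type` (name or code)
#' @param params a [dpd_params()]
#' @param noise shared unit-normal draw for the random term
#' @param dt time step (the random force carries the 1/sqrt(dt) scaling)
#' @return force 3-vector acting on `p_i`
#' @export
pairwise_dpd_force <- function(p_i, p_j, params, noise = 0, dt = 0.01) {
  rij <- p_i$pos - p_j$pos
  r <- sqrt(sum(rij^2))
  if (r == 0) stop("coincident particles: separation direction undefined")
  if (r >= params$rc) return(c(0, 0, 0))
  ti <- as_type_code(p_i$type %||% "solvent") + 1L
  tj <- as_type_code(p_j$type %||% "solvent") + 1L
  rhat <- rij / r
  wc <- 1 - r / params$rc
  wr <- wc^params$s
  vij <- p_i$vel - p_j$vel
  fc <- params$a[ti, tj] * wc
  fd <- -params$gamma[ti, tj] * wr^2 * sum(rhat * vij)
  fr <- params$sigma[ti, tj] * wr * noise / sqrt(dt)
  (fc + fd + fr) * rhat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neighbour pairs within a cutoff
#'
#' Cell-binned neighbour search returning every unordered particle pair with
#' minimum-image distance strictly below `cutoff`. Periodicity is honoured
#' per axis.
#'
#' @param system a [particle_system()] (or bare n x 3 position matrix)
#' @param cutoff interaction cutoff
#' @param box list with `lo`, `hi` (3-vectors) and `periodic`
#'   (3 logicals)
#' @return 2-column integer matrix of pair indices (i < j)
#' @export
build_neighbor_list <- function(system, cutoff, box) {
  pos <- if (inherits(system, "particle_system")) system$pos else as.matrix(system)
  lo <- box$lo; hi <- box$hi; per <- box$periodic
  len <- hi - lo
  if (any(per & len < 2 * cutoff)) {
    stop("cutoff exceeds half the box extent along a periodic axis ",
         "(minimum image ambiguous)")
  }
  n <- nrow(pos)
  if (n < 2) return(matrix(integer(0), 0, 2))
  nc <- pmax(1L, as.integer(floor(len / cutoff)))
  csz <- len / nc
  idx <- sapply(1:3, function(k) {
    v <- as.integer(floor((pos[, k] - lo[k]) / csz[k]))
    pmin(pmax(v, 0L), nc[k] - 1L)
  })
  key <- (idx[, 3] * nc[2] + idx[, 2]) * nc[1] + idx[, 1]
  bins <- split(seq_len(n), key)
  binkey <- as.numeric(names(bins))
  lookup <- new.env(hash = TRUE)
  for (b in seq_along(bins)) assign(as.character(binkey[b]), bins[[b]], lookup)
  out_i <- integer(0); out_j <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cut2 <- cutoff^2
  for (b in seq_along(bins)) {
    k <- binkey[b]
    cz <- k %/% (nc[1] * nc[2])
    cy <- (k - cz * nc[1] * nc[2]) %/% nc[1]
    cx <- k %% nc[1]
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      cc <- c(cx, cy, cz) + offs[o, ]
      for (kk in 1:3) {
        if (per[kk]) cc[kk] <- cc[kk] %% nc[kk]
      }
      if (any(cc < 0 | cc >= nc)) next
      kk2 <- (cc[3] * nc[2] + cc[2]) * nc[1] + cc[1]
      hit <- lookup[[as.character(kk2)]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- unique(cand)
    for (i in bins[[b]]) {
      js <- cand[cand > i]
      if (!length(js)) next
      d <- pos[js, , drop = FALSE] -
        matrix(pos[i, ], length(js), 3, byrow = TRUE)
      for (kk in 1:3) {
        if (per[kk]) d[, kk] <- d[, kk] - len[kk] * round(d[, kk] / len[kk])
      }
      keep <- rowSums(d^2) < cut2
      out_i <- c(out_i, rep.int(i, sum(keep)))
      out_j <- c(out_j, js[keep])
    }
  }
  cbind(i = out_i, j = out_j)
}

#' Advance particle positions and velocities by one step
#'
#' Velocity-Verlet step (the lambda = 1/2 modified scheme reduces to plain
#' velocity Verlet when forces are velocity-independent). Wall particles are
#' never moved; positions are wrapped along periodic axes.
#'
#' @param system a [particle_system()]
#' @param forces n x 3 force matrix at the current positions
#' @param dt time step (> 0)
#' @param force_fn optional function(system) giving forces at the drifted
#'   positions; when omitted the step treats `forces` as constant
#' @param box optional periodic box (as in [build_neighbor_list()])
#' @return the updated `particle_system`
#' @export
integrate_step <- function(system, forces, dt, force_fn = NULL, box = NULL) {
  stopifnot(dt > 0)
  forces <- as.matrix(forces)
  bad <- which(!is.finite(rowSums(forces)))
  if (length(bad)) {
    stop("non-finite force on particle ", bad[1])
  }
  mob <- system$type != PARTICLE_TYPES["wall"]
  im <- 1 / system$mass
  sys2 <- system
  sys2$pos[mob, ] <- system$pos[mob, ] + dt * system$vel[mob, ] +
    0.5 * dt^2 * im[mob] * forces[mob, ]
  if (!is.null(box)) {
    len <- box$hi - box$lo
    for (k in 1:3) {
      if (box$periodic[k]) {
        sys2$pos[, k] <- box$lo[k] + (sys2$pos[, k] - box$lo[k]) %% len[k]
      }
    }
  }
  fnew <- if (is.null(force_fn)) forces else as.matrix(force_fn(sys2))
  sys2$vel[mob, ] <- system$vel[mob, ] +
    0.5 * dt * im[mob] * (forces[mob, ] + fnew[mob, ])
  sys2
}

#' Kinetic temperature of the mobile particles
#'
#' Mean kinetic energy per particle per degree of freedom, doubled -- i.e.
#' the instantaneous kinetic temperature in model energy units, which in
#' equilibrium equals the thermostat target `kBT`.
#'
#' @param system a [particle_system()], or a list of them (frames averaged)
#' @return scalar temperature estimate in energy units
#' @export
measure_temperature <- function(system) {
  frames <- if (inherits(system, "particle_system")) list(system) else system
  if (!length(frames)) stop("empty frame window")
  ke <- vapply(frames, function(s) {
    mob <- s$type != PARTICLE_TYPES["wall"]
    if (!any(mob)) stop("no mobile particles in frame")
    sum(s$mass[mob] * rowSums(s$vel[mob, , drop = FALSE]^2)) /
      (3 * sum(mob))
  }, numeric(1))
  mean(ke)
}
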