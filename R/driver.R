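random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# disc-normal-along-y orientation with a small random tilt and a random
# spin; red cells must present their thin axis across the 5 um duct
duct_rotation <- function(max_tilt = 0.25) {
  flip <- diag(3)[, c(1, 3, 2)] # z -> y
  flip[, 3] <- -flip[, 3]       # keep det = +1
  sp <- runif(1, 0, 2 * pi)
  spin <- matrix(c(cos(sp), 0, -sin(sp), 0, 1, 0, sin(sp), 0, cos(sp)), 3, 3)
  tl <- runif(1, -max_tilt, max_tilt)
  tilt <- matrix(c(cos(tl), sin(tl), 0, -sin(tl), cos(tl), 0, 0, 0, 1), 3, 3)
  tilt %*% spin %*% flip
}

#' Place red blood cells at a prescribed hematocrit
#'
#' Rejection sampling of non-overlapping cell poses. The cell count is
#' `round(hematocrit * V_lumen / V0tot)`. Inside the narrow parent duct the
#' disc normal is constrained near the width axis (the only way an 8 um
#' disc fits a 5 um duct); inside the aneurysm body the orientation is
#' unconstrained. Placement is deterministic per seed.
#'
#' @param g an [build_ma_channel()] geometry
#' @param hematocrit target red-cell volume fraction
#' @param mesh template `triangulated_membrane` of the red cell
#' @param seed RNG seed
#' @param region `"lumen"` (whole lumen) or `"parent"` (parent duct only)
#' @param wall_margin minimum vertex clearance from the wall
#' @param cell_margin minimum vertex clearance between cells
#' @param max_tries rejection budget per cell
#' @return list of n x 3 vertex matrices, one per placed cell
#' @export
seed_rbcs <- function(g, hematocrit, mesh, seed = 1,
                      region = c("lumen", "parent"),
                      wall_margin = 0.25, cell_margin = 0.4,
                      max_tries = 2000) {
  region <- match.arg(region)
  n_cells <- round(hematocrit * g$lumen_volume / unname(mesh$volume))
  if (n_cells == 0) return(list())
  gv <- as_geom_vec(g)
  ymax <- if (g$R > 0) g$yc + g$R else g$r2
  V0 <- mesh$vertices
  V0 <- sweep(V0, 2, colMeans(V0)) # centre the template
  rad <- max(sqrt(rowSums(V0^2)))
  placed <- list()
  occ <- matrix(0, 0, 3)
  set.seed(seed)
  # margins tighten progressively for late cells: the soft DPD cores resolve
  # near-contacts during the first equilibration steps, so dense packings
  # only need to avoid outright interpenetration
  wmarg <- wall_margin
  cmarg <- cell_margin
  for (ci in seq_len(n_cells)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      if (try %% 500 == 0) {
        wmarg <- max(0.1, 0.75 * wmarg)
        cmarg <- max(0.12, 0.75 * cmarg)
      }
      cen <- c(runif(1, 0, g$length),
               runif(1, wmarg, ymax - wmarg),
               runif(1, wmarg, g$depth - wmarg))
      reg <- cpp_classify_points(gv, matrix(cen, 1, 3))
      if (reg == 0L) next
      if (region == "parent" && reg != 1L) next
      in_duct <- reg == 1L || g$R1 < 2.2 * rad
      rot <- if (in_duct) duct_rotation() else random_rotation()
      Vc <- V0 %*% t(rot)
      Vc <- sweep(Vc, 2, cen, "+") # x left unwrapped: bonded terms must
                                   # never straddle the periodic seam
      if (any(cpp_lumen_distance(gv, Vc) > -wmarg)) next
      if (nrow(occ) > 0) {
        # cross-cell clearance, x-periodic
        near <- which(abs(occ[, 2] - cen[2]) < 2 * rad + cmarg &
                        abs(occ[, 3] - cen[3]) < 2 * rad + cmarg)
        if (length(near)) {
          dx <- outer(Vc[, 1], occ[near, 1], "-")
          dx <- dx - g$length * round(dx / g$length)
          d2 <- dx^2 + outer(Vc[, 2], occ[near, 2], "-")^2 +
            outer(Vc[, 3], occ[near, 3], "-")^2
          if (min(d2) < cmarg^2) next
        }
      }
      placed[[ci]] <- Vc
      occ <- rbind(occ, Vc)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place red cell ", ci, " of ", n_cells,
           " without overlap; lower the hematocrit or enlarge the channel")
    }
  }
  placed
}

fill_solvent <- function(g, density, seed) {
  a <- density^(-1 / 3)
  ymax <- if (g$R > 0) g$yc + g$R else g$r2
  xs <- seq(a / 2, g$length, by = a)
  ys <- seq(a / 2, ymax, by = a)
  zs <- seq(a / 2, g$depth, by = a)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  set.seed(seed + 7L)
  pts <- pts + matrix(runif(length(pts), -0.3 * a, 0.3 * a), nrow(pts), 3)
  pts[, 1] <- pts[, 1] %% g$length
  keep <- cpp_classify_points(as_geom_vec(g), pts) > 0L
  pts[keep, , drop = FALSE]
}

cell_com <- function(pos, L) {
  # membrane coordinates are kept unwrapped along x, so the plain mean is
  # exact; report it wrapped into [0, L)
  c(mean(pos[, 1]) %% L, mean(pos[, 2]), mean(pos[, 3]))
}

#' Run a blood-flow simulation
#'
#' Assembles the scenario described by a [simulation_config()] -- wall
#' shell, solvent, red cells at the target hematocrit, platelet injection
#' schedule -- and integrates it, returning per-cell tracks, frames and a
#' final state usable as an exact-resume checkpoint. Runs are
#' bit-reproducible for a fixed config and seed.
#'
#' @param config a [simulation_config()]
#' @param resume a checkpoint (the `checkpoint` element of a previous
#'   result) to continue from
#' @param steps override the total step count (e.g. to stop early and
#'   checkpoint)
#' @return object of class `simulation_result`: `tracks` (data frame with
#'   cell id, type, frame, time, centre of mass, region), `frames`
#'   (optional full positions), `checkpoint`, `diag`
#' @export
run_simulation <- function(config, resume = NULL, steps = NULL) {
  g <- config$geometry
  us <- config$units
  gv <- as_geom_vec(g)
  total_steps <- as.integer(steps %||% config$steps)
  chunk <- config$output_every
  v_target <- to_model_velocity(us, config$drive$target_mm_s * 1e-3)
  dt <- config$dt

  if (is.null(resume)) {
    sc <- setup_scenario(config)
    st <- sc$state
    meshes <- sc$meshes
    cells <- sc$cells
    sched <- sc$sched
    ctrl <- list(g = 0.25 * v_target, v_prev = NA_real_)
    tracks <- list()
    frames <- list()
    step0 <- 0L
    rngR <- .Random.seed
  } else {
    st <- resume$state
    meshes <- resume$meshes
    cells <- resume$cells
    sched <- resume$sched
    ctrl <- resume$ctrl
    tracks <- resume$tracks
    frames <- resume$frames
    step0 <- resume$step
    assign(".Random.seed", resume$rngR, envir = globalenv())
    rngR <- resume$rngR
  }

  inter <- interaction_matrix(config$fluid, config$morse,
                              a_coupling = config$a_coupling %||% 10,
                              gamma_coupling = config$gamma_coupling %||% 20)
  wallpad <- config$fluid$rc + 0.6
  ymax <- if (g$R > 0) g$yc + g$R else g$r2
  box <- list(lo = c(0, -wallpad, -wallpad),
              hi = c(g$length, ymax + wallpad, g$depth + wallpad),
              periodic = c(TRUE, FALSE, FALSE))
  period_model <- to_model_time(us, config$drive$period_s)
  slab <- c(max(1, g$xc - g$h - g$r2 - 3), max(3, g$xc - g$h - 3))
  if (slab[2] <= slab[1]) slab <- c(1, 3)
  opts <- list(vmax = config$vmax, slab_x0 = slab[1], slab_x1 = slab[2],
               measure = TRUE, reflect_faces = TRUE)

  record <- function(step_now) {
    t_now <- step_now * dt
    for (ci in seq_along(cells)) {
      idx <- cells[[ci]]$idx
      com <- cell_com(st$pos[idx, , drop = FALSE], g$length)
      reg <- cpp_classify_points(gv, matrix(com, 1, 3))
      tracks[[length(tracks) + 1]] <<- data.frame(
        cell = ci, type = cells[[ci]]$type, frame = step_now %/% chunk,
        time = to_physical_time(us, t_now),
        x = com[1], y = com[2], z = com[3],
        region = c("outside", "parent", "ma_body")[reg + 1L],
        born_inside = cells[[ci]]$born_inside)
    }
    if (isTRUE(config$store_frames)) {
      frames[[length(frames) + 1]] <<- list(step = step_now, pos = st$pos,
                                            vel = st$vel, type = st$type)
    }
  }
  if (step0 == 0L) record(0L)

  unstable <- FALSE
  step_now <- step0
  topo <- NULL
  topo_n <- -1L
  while (step_now < total_steps) {
    if (length(cells) != topo_n) {
      topo <- if (length(cells)) {
        membrane_topology(meshes, lapply(cells, `[[`, "params"), us,
                          index_offset = vapply(cells, function(cc)
                            cc$idx[1] - 1L, integer(1)))
      }
      topo_n <- length(cells)
    }
    drv <- list(g = ctrl$g,
                pulse_amp = config$drive$amplitude,
                pulse_period = period_model,
                parent_only = TRUE, langevin_gamma = 0, langevin_kbt = 0)
    st <- cpp_run_chunk(st, if (is.null(topo)) list() else unclass(topo),
                        unclass(inter), box,
                        gv, drv, opts, chunk, dt)
    step_now <- step_now + st$diag$steps_done
    if (st$diag$unstable) {
      unstable <- TRUE
      break
    }
    record(step_now)
    ctrl <- body_force_controller(ctrl, v_target, st$diag$inlet_vx,
                                  dt_window = chunk * dt)
    ins <- process_injections(st, sched, cells, meshes, config,
                              step_now * dt, v_target, g)
    st <- ins$state; sched <- ins$sched; cells <- ins$cells
    meshes <- ins$meshes
  }

  checkpoint <- list(state = st, meshes = meshes, cells = cells,
                     sched = sched, ctrl = ctrl, tracks = tracks,
                     frames = frames, step = step_now, rngR = .Random.seed)
  tracks_df <- if (length(tracks)) do.call(rbind, tracks) else NULL
  structure(
    list(config = config, tracks = tracks_df, frames = frames,
         checkpoint = checkpoint,
         diag = list(unstable = unstable, steps = step_now,
                     body_force = ctrl$g, inlet_vx = st$diag$inlet_vx,
                     inlet_v_mm_s = to_physical_velocity(
                       us, st$diag$inlet_vx) * 1e3,
                     reflect_fail = st$diag$reflect_fail)),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d steps, %d cells tracked, inlet %.3g mm/s%s\n",
    x$diag$steps, length(unique(x$tracks$cell %||% integer(0))),
    x$diag$inlet_v_mm_s %||% NA,
    if (x$diag$unstable) " [UNSTABLE]" else ""))
  invisible(x)
}

setup_scenario <- function(config) {
  g <- config$geometry
  gv <- as_geom_vec(g)
  set.seed(config$seed)
  wall <- generate_wall_particles(g, thickness = config$fluid$rc,
                                  density = config$wall_density,
                                  rc = config$fluid$rc, seed = config$seed)
  solv <- fill_solvent(g, config$fluid$density, config$seed)
  set.seed(config$seed + 13L)
  meshes <- list()
  cells <- list()
  vert_list <- list()
  if (!is.null(config$rbc) && config$hematocrit > 0) {
    rbc_mesh <- build_cell_mesh(config$rbc$shape, config$rbc$n_vertices,
                                volume = config$rbc$V0tot,
                                aspect_ratio = config$rbc$aspect_ratio)
    pl <- seed_rbcs(g, config$hematocrit, rbc_mesh, seed = config$seed + 1L,
                    region = config$rbc_placement)
    for (Vc in pl) {
      m <- rbc_mesh
      m$vertices <- Vc
      meshes[[length(meshes) + 1]] <- m
      com <- cell_com(Vc, g$length)
      reg <- cpp_classify_points(gv, matrix(com, 1, 3))
      cells[[length(cells) + 1]] <- list(
        type = "rbc", params = config$rbc,
        born_inside = reg == 2L)
      vert_list[[length(vert_list) + 1]] <- Vc
    }
  }
  nv_cells <- vapply(vert_list, nrow, integer(1))
  n_sol <- nrow(solv); n_wall <- nrow(wall)
  pos <- do.call(rbind, c(list(solv, wall), vert_list))
  n <- nrow(pos)
  type <- c(rep(0L, n_sol), rep(1L, n_wall),
            rep(2L, sum(nv_cells)))
  cellid <- c(rep(0L, n_sol + n_wall),
              rep(seq_along(vert_list), nv_cells))
  off <- n_sol + n_wall
  for (ci in seq_along(cells)) {
    cells[[ci]]$idx <- off + seq_len(nv_cells[ci])
    off <- off + nv_cells[ci]
  }
  set.seed(config$seed + 29L)
  vel <- matrix(rnorm(3 * n, 0, sqrt(config$fluid$kBT)), n, 3)
  vel[type == 1L, ] <- 0
  vel[type >= 2L, ] <- 0
  mass <- rep(1, n)
  for (ci in seq_along(cells)) {
    mass[cells[[ci]]$idx] <- cells[[ci]]$params$vertex_mass %||% 1
  }
  st <- list(pos = pos, vel = vel, force = matrix(0, n, 3),
             mass = mass, type = type, cell = cellid,
             time = 0,
             rng = c(config$seed %% 65536, config$seed %/% 65536 + 1,
                     54, config$seed + 99),
             force_stale = TRUE)
  # platelet injection schedule (physical rate -> model times)
  us <- config$units
  t_total <- config$steps * config$dt
  sched <- list(times = numeric(0), next_i = 1L,
                template = NULL)
  if (!is.null(config$platelet) && config$platelet_rate > 0) {
    dt_inj <- to_model_time(us, 1 / config$platelet_rate)
    sched$times <- seq(dt_inj, t_total, by = dt_inj)
    sched$template <- build_cell_mesh(
      config$platelet$shape, config$platelet$n_vertices,
      volume = config$platelet$V0tot,
      aspect_ratio = config$platelet$aspect_ratio)
  }
  list(state = st, meshes = meshes, cells = cells, sched = sched)
}

process_injections <- function(st, sched, cells, meshes, config, t_now,
                               v_target, g) {
  while (sched$next_i <= length(sched$times) &&
         sched$times[sched$next_i] <= t_now) {
    tmpl <- sched$template
    V0 <- sweep(tmpl$vertices, 2, colMeans(tmpl$vertices))
    rad <- max(sqrt(rowSums(V0^2)))
    placedok <- FALSE
    for (try in 1:20) {
      cen <- c(runif(1, 1, 3),
               runif(1, rad + 0.3, g$r2 - rad - 0.3),
               runif(1, rad + 0.3, g$depth - rad - 0.3))
      rot <- random_rotation()
      Vc <- sweep(V0 %*% t(rot), 2, cen, "+")
      # clearance from existing membranes
      clear <- TRUE
      for (cc in cells) {
        idx <- cc$idx
        com_d <- abs(cell_com(st$pos[idx, , drop = FALSE], g$length) - cen)
        com_d[1] <- min(com_d[1], g$length - com_d[1])
        if (sqrt(sum(com_d^2)) > 2 * rad + 4) next
        d2 <- outer(Vc[, 1], st$pos[idx, 1], "-")^2 +
          outer(Vc[, 2], st$pos[idx, 2], "-")^2 +
          outer(Vc[, 3], st$pos[idx, 3], "-")^2
        if (min(d2) < 0.36) {
          clear <- FALSE
          break
        }
      }
      if (clear) {
        placedok <- TRUE
        break
      }
    }
    if (!placedok) break # blocked inlet: defer to the next chunk
    nvp <- nrow(Vc)
    m <- tmpl
    m$vertices <- Vc
    meshes[[length(meshes) + 1]] <- m
    newid <- length(cells) + 1L
    cells[[newid]] <- list(type = "platelet", params = config$platelet,
                           born_inside = FALSE,
                           idx = nrow(st$pos) + seq_len(nvp))
    st$pos <- rbind(st$pos, Vc)
    vin <- matrix(0, nvp, 3)
    vin[, 1] <- v_target
    st$vel <- rbind(st$vel, vin)
    st$force <- rbind(st$force, matrix(0, nvp, 3))
    st$mass <- c(st$mass, rep(config$platelet$vertex_mass %||% 1, nvp))
    st$type <- c(st$type, rep(3L, nvp))
    st$cell <- c(st$cell, rep(newid, nvp))
    st$force_stale <- TRUE
    sched$next_i <- sched$next_i + 1L
  }
  list(state = st, sched = sched, cells = cells, meshes = meshes)
}

#' Preset simulation scenarios
#'
#' Named parameter combinations covering the study design: four channel
#' sizes (BNR 2.2, 3, 5.4, 8), four inlet velocities (0.25, 0.75, 1.5,
#' 2.0 mm/s) and six biomechanical scenarios at 1.5 mm/s --
#' `"adhesion-off"` (baseline, Ht 40 percent), `"adhesion-on"`,
#' `"adhesion-stiff"` (adhesion plus 5x shear modulus), `"ht20"`, `"ht10"`,
#' and `"ht10-pulsatile"`. The `"mini"` scale reduces solvent density, cell
#' mesh resolution and run length for desk-scale work while preserving
#' geometry, hematocrit and the driving velocity; `"full"` matches the
#' study-scale protocol (50 million steps) and is intended for cluster use.
#'
#' @param scenario scenario id (see Details)
#' @param bnr body-to-neck ratio of the channel
#' @param velocity_mm_s target inlet velocity
#' @param scale `"mini"` or `"full"`
#' @param seed RNG seed
#' @return a [simulation_config()]
#' @export
preset_scenario <- function(scenario = c("adhesion-off", "adhesion-on",
                                         "adhesion-stiff", "ht20", "ht10",
                                         "ht10-pulsatile"),
                            bnr = 8, velocity_mm_s = 1.5,
                            scale = c("mini", "full"), seed = 1) {
  scenario <- match.arg(scenario)
  scale <- match.arg(scale)
  stopifnot(bnr %in% c(2.2, 3, 5.4, 8))
  ht <- switch(scenario, ht20 = 0.2, ht10 = 0.1, `ht10-pulsatile` = 0.1, 0.4)
  adhesion <- scenario %in% c("adhesion-on", "adhesion-stiff")
  rbc_preset <- if (scenario == "adhesion-stiff") "rbc_diabetic" else "rbc_normal"
  drv <- if (scenario == "ht10-pulsatile") {
    flow_drive(velocity_mm_s, "pulsatile")
  } else {
    flow_drive(velocity_mm_s)
  }
  if (scale == "mini") {
    make_mini_ma(bnr, hematocrit = ht, velocity_mm_s = velocity_mm_s,
                 adhesion = adhesion,
                 stiff = scenario == "adhesion-stiff",
                 pulsatile = scenario == "ht10-pulsatile",
                 seed = seed)
  } else {
    simulation_config(
      geometry = build_ma_channel(bnr),
      morse = morse_params(enabled = adhesion),
      rbc = cell_params(rbc_preset),
      hematocrit = ht,
      rbc_placement = "lumen",
      platelet_rate = 300,
      drive = drv, dt = 0.005, steps = 5e7, output_every = 10000,
      seed = seed)
  }
}
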