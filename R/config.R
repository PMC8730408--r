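#' Simulation configuration
#'
#' Bundles everything a run needs: geometry, unit system, fluid parameters,
#' cell presets and hematocrit, adhesion, driving, and run control. All
#' randomness (cell placement, initial velocities, thermal noise, platelet
#' injection) derives from the single `seed`.
#'
#' @param geometry an [build_ma_channel()] channel (or `straight_duct()`)
#' @param units a [unit_system()]
#' @param fluid a [dpd_params()]
#' @param morse a [morse_params()] (set `enabled = FALSE` for no adhesion)
#' @param rbc a [cell_params()] red-cell preset (NULL: no red cells)
#' @param platelet a [cell_params()] platelet preset (NULL: no platelets)
#' @param hematocrit red-cell volume fraction of the lumen, in (0, 0.65)
#' @param rbc_placement `"lumen"` (fill parent and body) or `"parent"`
#' @param platelet_rate platelet injections per physical second at the inlet
#' @param drive a [flow_drive()]
#' @param dt integration time step, model units
#' @param steps total integration steps
#' @param output_every frames cadence, steps (must divide `steps`)
#' @param seed integer RNG seed
#' @param wall_density wall particle number density
#' @param vmax instability threshold on particle speed (model units)
#' @param store_frames keep full particle frames (memory heavy) or only
#'   cell tracks
#' @param a_coupling,gamma_coupling solvent-membrane conservative amplitude
#'   and friction (see [interaction_matrix()])
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(geometry,
                              units = unit_system(),
                              fluid = dpd_params(),
                              morse = morse_params(enabled = FALSE),
                              rbc = cell_params("rbc_normal"),
                              platelet = cell_params("platelet"),
                              hematocrit = 0.4,
                              rbc_placement = c("lumen", "parent"),
                              platelet_rate = 300,
                              drive = flow_drive(1.5),
                              dt = 0.005,
                              steps = 10000,
                              output_every = 200,
                              seed = 1,
                              wall_density = NULL,
                              vmax = 50,
                              store_frames = FALSE,
                              a_coupling = 10,
                              gamma_coupling = 20) {
  rbc_placement <- match.arg(rbc_placement)
  if (!is.null(rbc)) stopifnot(hematocrit > 0, hematocrit < 0.65)
  if (steps %% output_every != 0) {
    stop("output_every must divide steps")
  }
  structure(
    list(geometry = geometry, units = units, fluid = fluid, morse = morse,
         rbc = rbc, platelet = platelet, hematocrit = hematocrit,
         rbc_placement = rbc_placement, platelet_rate = platelet_rate,
         drive = drive, dt = dt, steps = as.integer(steps),
         output_every = as.integer(output_every), seed = as.integer(seed),
         wall_density = wall_density %||% fluid$density, vmax = vmax,
         store_frames = store_frames,
         a_coupling = a_coupling, gamma_coupling = gamma_coupling),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> BNR=%s Ht=%g%% v=%g mm/s (%s) adhesion=%s\n",
    format(x$geometry$bnr), 100 * x$hematocrit, x$drive$target_mm_s,
    x$drive$mode, x$morse$enabled))
  cat(sprintf("  dt=%g steps=%d seed=%d output every %d steps\n",
              x$dt, x$steps, x$seed, x$output_every))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' Flat, human-editable serialisation of the scalar fields of a
#' [simulation_config()]; `read_config_yaml` reconstructs the full object
#' through the standard constructors.
#'
#' @param config a [simulation_config()]
#' @param path file path
#' @export
write_config_yaml <- function(config, path) {
  g <- config$geometry
  obj <- list(
    geometry = list(bnr = g$bnr, r2 = g$r2, depth = g$depth,
                    neck_width = g$neck_width, length = g$length),
    dpd = list(a = config$fluid$a[1, 1], gamma = config$fluid$gamma[1, 1],
               kBT = config$fluid$kBT, rc = config$fluid$rc,
               s = config$fluid$s, density = config$fluid$density,
               dt = config$dt, seed = config$seed),
    interactions = list(morse = list(
      De = config$morse$De, beta = config$morse$beta, r0 = config$morse$r0,
      rcut = config$morse$rcut, enabled = config$morse$enabled)),
    cells = list(
      hematocrit = config$hematocrit,
      rbc_preset = if (is.null(config$rbc)) NULL else config$rbc$preset,
      rbc_vertices = if (is.null(config$rbc)) NULL else config$rbc$n_vertices,
      placement = config$rbc_placement,
      platelet_rate = config$platelet_rate),
    drive = list(mode = config$drive$mode,
                 target_mm_s = config$drive$target_mm_s,
                 amplitude = config$drive$amplitude,
                 period_s = config$drive$period_s),
    run = list(steps = config$steps, output_every = config$output_every,
               vmax = config$vmax)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- if (is.null(y$geometry$bnr) || is.na(y$geometry$bnr)) {
    straight_duct(y$geometry$r2, y$geometry$depth, y$geometry$length)
  } else {
    build_ma_channel(y$geometry$bnr, y$geometry$r2, y$geometry$depth,
                     y$geometry$neck_width, y$geometry$length)
  }
  rbc <- if (is.null(y$cells$rbc_preset)) NULL else {
    cell_params(y$cells$rbc_preset, n_vertices = y$cells$rbc_vertices)
  }
  simulation_config(
    geometry = geom,
    fluid = dpd_params(a = y$dpd$a, gamma = y$dpd$gamma, kBT = y$dpd$kBT,
                       rc = y$dpd$rc, s = y$dpd$s, density = y$dpd$density),
    morse = morse_params(De = y$interactions$morse$De,
                         beta = y$interactions$morse$beta,
                         r0 = y$interactions$morse$r0,
                         rcut = y$interactions$morse$rcut,
                         enabled = y$interactions$morse$enabled),
    rbc = rbc,
    hematocrit = y$cells$hematocrit,
    rbc_placement = y$cells$placement,
    platelet_rate = y$cells$platelet_rate,
    drive = flow_drive(y$drive$target_mm_s, y$drive$mode,
                       amplitude = y$drive$amplitude,
                       period_s = y$drive$period_s),
    dt = y$dpd$dt, steps = y$run$steps, output_every = y$run$output_every,
    seed = y$dpd$seed, vmax = y$run$vmax
  )
}
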