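#' Model/physical unit mapping
#'
#' The simulation works in reduced (model) units; geometry is most convenient
#' when one model length equals one micrometre, and the thermal energy scale
#' is anchored to body temperature. A `unit_system` fixes three independent
#' scales -- length (um per model unit), energy (J per model unit) and mass
#' (kg per model unit) -- and derives the time scale as
#' `time = length * sqrt(mass / energy)` (SI), which is the unique
#' combination with dimensions of time.
#'
#' The default mass scale (1e-15 kg, roughly the plasma mass contained in one
#' cubic micrometre) places physiological capillary flow velocities
#' (0.25--2 mm/s) at 0.1--1 in model units, i.e. at or below the thermal
#' velocity of a unit-mass particle at `kBT = 1`, which keeps the DPD fluid
#' well inside its quasi-incompressible operating regime.
#'
#' @param length_um model length unit, in micrometres
#' @param temperature_K temperature anchoring the energy unit to `kB * T`
#' @param mass_kg model mass unit, in kilograms
#' @return an object of class `unit_system` with fields `length_scale` (um),
#'   `energy_scale` (J), `mass_scale` (kg) and the derived `time_scale` (s)
#' @examples
#' us <- unit_system()
#' # physical time of 10000 steps at dt = 0.005
#' 10000 * 0.005 * us$time_scale
#' @export
unit_system <- function(length_um = 1, temperature_K = 310, mass_kg = 1e-15) {
  stopifnot(length_um > 0, temperature_K > 0, mass_kg > 0)
  energy <- kBOLTZ * temperature_K
  time <- (length_um * 1e-6) * sqrt(mass_kg / energy)
  structure(
    list(
      length_scale = length_um,
      energy_scale = energy,
      mass_scale = mass_kg,
      time_scale = time
    ),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  length: %g um   energy: %g J   mass: %g kg\n",
              x$length_scale, x$energy_scale, x$mass_scale))
  cat(sprintf("  derived time: %g s per model unit\n", x$time_scale))
  invisible(x)
}

#' Convert between physical and model units
#'
#' `to_model_*` map physical SI quantities into model units under a
#' `unit_system`; `to_physical_*` invert them exactly.
#'
#' @param us a [unit_system()]
#' @param x quantity to convert (length in um for the length converters,
#'   otherwise SI: seconds, m/s)
#' @return converted numeric vector
#' @export
to_model_length <- function(us, x) x / us$length_scale

#' @rdname to_model_length
#' @export
to_physical_length <- function(us, x) x * us$length_scale

#' @rdname to_model_length
#' @export
to_model_time <- function(us, x) x / us$time_scale

#' @rdname to_model_length
#' @export
to_physical_time <- function(us, x) x * us$time_scale

#' @rdname to_model_length
#' @export
to_model_velocity <- function(us, x) {
  x * us$time_scale / (us$length_scale * 1e-6)
}

#' @rdname to_model_length
#' @export
to_physical_velocity <- function(us, x) {
  x * (us$length_scale * 1e-6) / us$time_scale
}
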