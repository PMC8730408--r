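#' Build a microaneurysm channel geometry
#'
#' The channel is a rectangular parent capillary (width `r2` across y, depth
#' `depth` across z, periodic along the flow direction x) carrying a
#' saccular body: a circular bulge of diameter `R1 = bnr * r2` in the x-y
#' plane, extruded through the full channel depth, opening into the parent
#' duct through a neck of width `neck_width` in the y = r2 wall. This
#' front-view-circle / side-view-rectangle construction mirrors
#' microfluidic-style channels of constant depth. The body-to-neck ratio
#' `BNR = R1 / r2` is the single geometric descriptor of aneurysm size; the
#' four simulated sizes are BNR 2.2, 3, 5.4 and 8, i.e. body diameters
#' 11--40 um on a 5 um parent vessel.
#'
#' @param bnr body-to-neck ratio (>= 1)
#' @param r2 parent vessel width, um
#' @param depth channel depth, um
#' @param neck_width neck opening width, um; default is 15 um capped at
#'   95 percent of the body diameter (the cap binds only for the smallest
#'   body, which could not physically carry a 15 um neck)
#' @param length channel period along x, um; default `4 * max(R1,
#'   neck_width) + 20` so the body does not interact with its own periodic
#'   image
#' @return object of class `ma_channel`: parent dimensions, `R1`, `bnr`,
#'   neck half-width `h`, body centre (`xc`, `yc`), body radius `R`, and the
#'   analytic lumen volume
#' @examples
#' g <- build_ma_channel(2.2)
#' g$R1 # 11 um
#' @export
build_ma_channel <- function(bnr, r2 = 5, depth = 10, neck_width = NULL,
                             length = NULL) {
  stopifnot(bnr >= 1, r2 > 0, depth > 0)
  R1 <- bnr * r2
  if (is.null(neck_width)) neck_width <- min(15, 0.95 * R1)
  if (neck_width > R1) stop("neck opening cannot be wider than the body")
  if (is.null(length)) length <- 4 * max(R1, neck_width) + 20
  if (length <= neck_width) stop("channel length must exceed the neck width")
  R <- R1 / 2
  h <- neck_width / 2
  d <- sqrt(max(0, R^2 - h^2)) # body-centre height above the wall plane
  xc <- length / 2
  yc <- r2 + d
  seg_below <- R^2 * acos(min(1, d / R)) - d * sqrt(max(0, R^2 - d^2))
  body_area <- pi * R^2 - seg_below
  structure(
    list(r2 = r2, depth = depth, length = length,
         R1 = R1, bnr = bnr, neck_width = neck_width,
         xc = xc, yc = yc, R = R, h = h,
         lumen_volume = (length * r2 + body_area) * depth,
         body_volume = body_area * depth),
    class = "ma_channel"
  )
}

#' @export
print.ma_channel <- function(x, ...) {
  cat(sprintf(
    "<ma_channel> BNR=%.2g: parent %g x %g um, body diameter %g um, neck %g um, L=%g um\n",
    x$bnr, x$r2, x$depth, x$R1, x$neck_width, x$length))
  cat(sprintf("  lumen volume %.0f um^3 (body %.0f um^3)\n",
              x$lumen_volume, x$body_volume))
  invisible(x)
}

geometry_vec <- function(g) {
  c(L = g$length, R2 = g$r2, depth = g$depth, has_body = 1,
    xc = g$xc, yc = g$yc, R = g$R, h = g$h)
}

# straight duct (no body) as a degenerate geometry
straight_duct <- function(r2 = 5, depth = 10, length = 20) {
  structure(
    list(r2 = r2, depth = depth, length = length, R1 = 0, bnr = NA,
         neck_width = 0, xc = length / 2, yc = r2, R = 0, h = 0,
         lumen_volume = length * r2 * depth, body_volume = 0),
    class = "ma_channel"
  )
}

duct_vec <- function(g) {
  v <- geometry_vec(g)
  v["has_body"] <- 0
  v
}

as_geom_vec <- function(g) {
  if (is.na(g$bnr) || g$R <= 0) duct_vec(g) else geometry_vec(g)
}

#' Classify points against the channel lumen
#'
#' Deterministic partition of space into parent lumen, aneurysm body lumen
#' and wall/outside. The boundary between the two lumen regions is the neck
#' surface (the rectangle y = r2, |x - xc| < h across the full depth): a
#' continuous path from parent to body flips its classification exactly
#' there.
#'
#' @param g an [build_ma_channel()] geometry
#' @param p point (3-vector) or n x 3 matrix of points
#' @return character vector: `"parent"`, `"ma_body"` or `"outside"`
#' @export
classify_point <- function(g, p) {
  p <- if (is.null(dim(p))) matrix(p, 1, 3) else as.matrix(p)
  code <- cpp_classify_points(as_geom_vec(g), p)
  c("outside", "parent", "ma_body")[code + 1L]
}

#' Frozen wall particles for the no-slip boundary
#'
#' Fills a shell of the given thickness outside the lumen with frozen
#' particles on a jittered grid at the requested number density. Together
#' with bounce-back reflection of fluid particles at the lumen surface this
#' imposes the no-slip condition; the shell must be at least one fluid
#' cutoff thick so fluid near the wall never sees vacuum.
#'
#' @param g an [build_ma_channel()] geometry
#' @param thickness shell thickness, um (>= `rc`)
#' @param density wall particle number density, per um^3
#' @param rc fluid interaction cutoff (for the thickness check)
#' @param seed RNG seed for the deterministic jitter
#' @return n x 3 matrix of wall particle positions
#' @export
generate_wall_particles <- function(g, thickness = 1, density = 3, rc = 1,
                                    seed = 1) {
  if (thickness < rc) {
    stop("wall shell thinner than the fluid cutoff: fluid would see vacuum")
  }
  a <- density^(-1 / 3)
  ymax <- if (g$R > 0) max(g$r2, g$yc + g$R) else g$r2
  xs <- seq(a / 2, g$length, by = a)
  ys <- seq(-thickness + a / 2, ymax + thickness, by = a)
  zs <- seq(-thickness + a / 2, g$depth + thickness, by = a)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  set.seed(seed)
  pts <- pts + matrix(runif(length(pts), -0.3 * a, 0.3 * a), nrow(pts), 3)
  pts[, 1] <- pts[, 1] %% g$length
  d <- cpp_lumen_distance(as_geom_vec(g), pts)
  pts[d > 0 & d <= thickness, , drop = FALSE]
}

#' Flow driving specification
#'
#' Static or pulsatile pressure-gradient driving, expressed as a target mean
#' inlet velocity in the parent vessel. The pulsatile mode modulates the
#' body force by `1 + amplitude * sin(2 pi t / period)`, whose time average
#' over whole periods equals the static drive exactly.
#'
#' @param target_mm_s target mean inlet velocity, mm/s (physical)
#' @param mode `"static"` or `"pulsatile"`
#' @param amplitude pulsatile amplitude fraction in `[0, 1)`
#' @param period_s pulsatile period, seconds (cardiac-scale default 1 s)
#' @return object of class `flow_drive`
#' @export
flow_drive <- function(target_mm_s = 1.5, mode = c("static", "pulsatile"),
                       amplitude = 0.3, period_s = 1) {
  mode <- match.arg(mode)
  stopifnot(target_mm_s > 0, amplitude >= 0, amplitude < 1)
  if (mode == "pulsatile" && period_s <= 0) stop("pulsatile period must be > 0")
  structure(list(mode = mode, target_mm_s = target_mm_s,
                 amplitude = if (mode == "pulsatile") amplitude else 0,
                 period_s = period_s),
            class = "flow_drive")
}

#' Instantaneous pulsatile force scale
#'
#' @param drive a [flow_drive()]
#' @param t time (same units as the period stored in `drive`)
#' @param period period override (defaults to the drive's period)
#' @return scale factor `1 + amplitude * sin(2 pi t / period)`
#' @export
pulsatile_modulation <- function(drive, t, period = NULL) {
  period <- period %||% drive$period_s
  if (drive$amplitude > 0 && period <= 0) stop("period must be positive")
  if (drive$amplitude == 0) return(rep(1, length(t)))
  1 + drive$amplitude * sin(2 * pi * t / period)
}

#' Adaptive update of the driving body force
#'
#' Adjusts the body-force magnitude toward a target mean inlet velocity.
#' The mean flow obeys the momentum balance
#' \eqn{d\bar v/dt = g - \bar v/\tau} with an unknown drag time constant
#' \eqn{\tau} (set by the channel resistance); because \eqn{\tau} is much
#' longer than a measurement window, fixed-gain feedback limit-cycles.
#' Instead the controller estimates \eqn{\tau} online from the current
#' force, mean velocity and its trend, and relaxes the force toward the
#' value `target / tau` that sustains the target -- a proportional-integral
#' action whose gain adapts to the measured channel drag.
#'
#' @param state list with `g` (current force per unit mass) and `v_prev`
#'   (previous window's measurement, `NA` initially)
#' @param target target mean inlet velocity (model units)
#' @param measured measured mean inlet velocity over the trailing window;
#'   non-finite measurements leave the force unchanged
#' @param dt_window time between measurements (model units)
#' @param relax fractional step toward the estimated sustaining force
#' @return updated state list
#' @export
body_force_controller <- function(state, target, measured, dt_window = 1,
                                  relax = 0.5) {
  if (!is.finite(measured)) return(state)
  vp <- state$v_prev %||% NA_real_
  state$v_prev <- measured
  if (is.finite(vp) && measured > 0.02 * target && state$g > 0) {
    dvdt <- (measured - vp) / dt_window
    denom <- state$g - dvdt
    if (denom > 1e-10) {
      tau <- measured / denom
      if (tau > 0) {
        g_need <- target / tau
        g_new <- (1 - relax) * state$g + relax * g_need
        state$g <- min(max(g_new, state$g / 3), state$g * 3)
        return(state)
      }
    }
  }
  # cold start / stalled flow: scale the force toward the target
  if (measured < target) state$g <- state$g * 1.5
  else state$g <- state$g * max(0.6, target / measured)
  state
}
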