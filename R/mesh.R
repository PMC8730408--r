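#' Build a closed triangulated cell membrane mesh
#'
#' Vertices are spread quasi-uniformly on the unit sphere (Fibonacci lattice
#' followed by pairwise-repulsion relaxation), triangulated by convex hull,
#' and the spherical mesh is then mapped onto the requested shape family.
#' The construction guarantees exactly `n_vertices` vertices and, by Euler's
#' formula for closed triangulations, `2 n - 4` faces and `3 n - 6` edges.
#'
#' Shape families:
#' \describe{
#'   \item{sphere}{`diameter` sets the size.}
#'   \item{oblate}{axisymmetric ellipsoid; `aspect_ratio` = thickness /
#'     diameter of the generated mesh (enforced exactly on the mesh bounding
#'     dimensions), `volume` sets the size. The resting platelet shape.}
#'   \item{biconcave}{the classical biconcave-disc parametrisation
#'     \eqn{z(\rho) = \pm \frac{D_0}{2}\sqrt{1-\hat\rho^2}
#'     (c_0 + c_1\hat\rho^2 + c_2\hat\rho^4)} with
#'     \eqn{c_0 = 0.207, c_1 = 2.003, c_2 = -1.123}, scaled uniformly so the
#'     mesh volume matches `volume`. The resting red-cell shape.}
#' }
#'
#' @param shape one of `"sphere"`, `"oblate"`, `"biconcave"`
#' @param n_vertices number of membrane vertices (>= 12)
#' @param diameter sphere diameter (um); ignored for other families
#' @param aspect_ratio thickness/diameter for the oblate family
#' @param volume target mesh volume (um^3) for oblate and biconcave
#' @return object of class `triangulated_membrane`: `vertices` (n x 3),
#'   `faces` (F x 3, outward-oriented), `edges` (E x 2), `dihedrals`
#'   (D x 4: shared edge a-b, flank of face (a,b,c), flank of face (b,a,d)),
#'   `l0` reference edge lengths, `theta0` reference dihedral angles, and the
#'   reference `area`/`volume` of the built shape
#' @examples
#' m <- build_cell_mesh("sphere", 60, diameter = 2)
#' mesh_area_volume(m)
#' @export
build_cell_mesh <- function(shape = c("sphere", "oblate", "biconcave"),
                            n_vertices,
                            diameter = 1,
                            aspect_ratio = 0.38,
                            volume = NULL) {
  shape <- match.arg(shape)
  if (n_vertices < 12) {
    stop("n_vertices must be >= 12: no closed triangulation target below ",
         "the icosahedral count")
  }
  iters <- if (n_vertices <= 150) 300L else 150L
  raw <- cpp_sphere_mesh(as.integer(n_vertices), iters, 0.15)
  V <- raw$vertices
  F <- raw$faces

  if (shape == "sphere") {
    V <- V * (diameter / 2)
  } else if (shape == "oblate") {
    if (!(aspect_ratio > 0 && aspect_ratio <= 1)) {
      stop("aspect_ratio must be in (0, 1]")
    }
    if (is.null(volume)) volume <- 6
    a <- (3 * volume / (4 * pi * aspect_ratio))^(1 / 3)
    cax <- a * aspect_ratio
    V <- revolve_equal_area(V, function(s) a * sin(pi * s),
                            function(s) cax * cos(pi * s))
    # enforce the aspect ratio exactly on the mesh bounding dimensions
    dia <- max(diff(range(V[, 1])), diff(range(V[, 2])))
    thk <- diff(range(V[, 3]))
    V[, 3] <- V[, 3] * (aspect_ratio * dia) / thk
    V <- V * (volume / mesh_volume_raw(V, F))^(1 / 3)
  } else {
    if (is.null(volume)) volume <- 92.5
    V <- revolve_equal_area(V, biconcave_rho, biconcave_z)
    V <- V * (volume / mesh_volume_raw(V, F))^(1 / 3)
  }

  if (mesh_volume_raw(V, F) < 0) F <- F[, c(1, 3, 2)]
  m <- structure(list(vertices = V, faces = F), class = "triangulated_membrane")
  m$edges <- mesh_edges(F)
  m$dihedrals <- mesh_dihedrals(F)
  m$l0 <- sqrt(rowSums((V[m$edges[, 1], ] - V[m$edges[, 2], ])^2))
  m$theta0 <- mesh_dihedral_angles(m)
  av <- mesh_area_volume(m)
  m$area <- av["area"]
  m$volume <- av["volume"]
  m$shape <- shape
  m
}

#' @export
print.triangulated_membrane <- function(x, ...) {
  cat(sprintf(
    "<triangulated_membrane> %s: %d vertices, %d faces, %d edges; A=%.3f V=%.3f\n",
    x$shape %||% "mesh", nrow(x$vertices), nrow(x$faces), nrow(x$edges),
    x$area, x$volume))
  invisible(x)
}

# biconcave-disc profile (classical red-cell parametrisation), D0 = 7.82 um:
# half-thickness z(q) = D0 sqrt(1-q^2) (a0 + a1 (q/2)^2 + a2 (q/2)^4) with
# q = 2 rho / D0 and a0 = 0.0518, a1 = 2.0026, a2 = -4.491, giving dimple
# thickness 0.81 um, maximum thickness 2.6 um, A ~ 134 um^2, V ~ 94 um^3
biconcave_f <- function(rho, D0 = 7.82) {
  q <- pmin(rho / (D0 / 2), 1)
  D0 * sqrt(pmax(0, 1 - q^2)) *
    (0.0518 + 2.0026 * (q / 2)^2 - 4.491 * (q / 2)^4)
}
# meridian parametrised by s in [0, 1]: top sheet pole -> rim -> bottom pole
biconcave_rho <- function(s, D0 = 7.82) (D0 / 2) * (1 - abs(2 * s - 1))
biconcave_z <- function(s, D0 = 7.82) {
  sign(0.5 - s) * biconcave_f(biconcave_rho(s, D0), D0)
}

# Map a unit-sphere mesh onto a surface of revolution so that vertex density
# follows the surface-area density: the sphere's uniform-in-z property means
# t = (1 - z)/2 is a cumulative-area coordinate, which is matched to the
# cumulative area of the target profile by quadrature.
revolve_equal_area <- function(V, rho_fun, z_fun, n_s = 4000) {
  s <- seq(0, 1, length.out = n_s)
  rho <- rho_fun(s)
  zz <- z_fun(s)
  ds <- sqrt(diff(rho)^2 + diff(zz)^2)
  rbar <- (rho[-1] + rho[-n_s]) / 2
  cumA <- c(0, cumsum(2 * pi * rbar * ds))
  t_of_s <- cumA / cumA[n_s]
  t <- pmin(pmax((1 - V[, 3]) / 2, 0), 1)
  rho_v <- stats::approx(t_of_s, rho, xout = t, rule = 2, ties = "ordered")$y
  z_v <- stats::approx(t_of_s, zz, xout = t, rule = 2, ties = "ordered")$y
  phi <- atan2(V[, 2], V[, 1])
  cbind(rho_v * cos(phi), rho_v * sin(phi), z_v)
}

mesh_volume_raw <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

mesh_edges <- function(F) {
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# For every undirected edge, the two incident faces and their flank
# vertices. The directed edge (a, b) belongs to the face listed as
# (a, b, c); the twin (b, a) to (b, a, d) -- matching the orientation
# convention of the bending-energy kernel.
mesh_dihedrals <- function(F) {
  nF <- nrow(F)
  dir_e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  flank <- c(F[, 3], F[, 1], F[, 2])
  key <- paste(pmin(dir_e[, 1], dir_e[, 2]), pmax(dir_e[, 1], dir_e[, 2]))
  sp <- split(seq_len(3 * nF), key)
  out <- matrix(0L, length(sp), 4)
  r <- 0L
  for (idx in sp) {
    if (length(idx) != 2) {
      stop("mesh is not closed: an edge is shared by ", length(idx), " faces")
    }
    r <- r + 1L
    a <- dir_e[idx[1], 1]; b <- dir_e[idx[1], 2]
    if (!(dir_e[idx[2], 1] == b && dir_e[idx[2], 2] == a)) {
      stop("inconsistent face orientation at an edge")
    }
    out[r, ] <- c(a, b, flank[idx[1]], flank[idx[2]])
  }
  out
}

#' Signed dihedral angles of a mesh
#'
#' Angle between adjacent face normals across every interior edge, signed by
#' the edge direction; zero for coplanar faces, positive for a convex hinge
#' of an outward-oriented mesh.
#'
#' @param m a `triangulated_membrane` (or list with `vertices`, `dihedrals`)
#' @return numeric vector, one angle per dihedral
#' @export
mesh_dihedral_angles <- function(m) {
  V <- m$vertices
  d <- m$dihedrals
  apply(d, 1, function(q) {
    a <- V[q[1], ]; b <- V[q[2], ]; cc <- V[q[3], ]; dd <- V[q[4], ]
    e <- b - a
    n1 <- cross3(b - a, cc - a)
    n2 <- cross3(dd - a, b - a)
    cs <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
    sn <- sum(cross3(n1, n2) * e) /
      (sqrt(sum(n1^2)) * sqrt(sum(n2^2)) * sqrt(sum(e^2)))
    atan2(sn, cs)
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Surface area and signed volume of a closed mesh
#'
#' Area is the sum of triangle areas; volume is the signed
#' divergence-theorem sum over oriented faces (positive for outward
#' orientation).
#'
#' @param m a `triangulated_membrane`, or a list with `vertices` and `faces`
#' @return named vector `c(area, volume)` in um^2 / um^3
#' @export
mesh_area_volume <- function(m) {
  V <- m$vertices
  F <- m$faces
  # closedness audit: every edge incident to exactly two faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(key) != 2)) stop("mesh is not closed")
  ab <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  ac <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  c(area = sum(sqrt(rowSums(cr^2))) / 2, volume = mesh_volume_raw(V, F))
}

#' Reduced volume of a closed shape
#'
#' \eqn{v = 6\sqrt{\pi} V / A^{3/2}}: 1 for a sphere, about 0.64 for the
#' resting red blood cell implied by A = 132.9 um^2 and V = 92.5 um^3.
#'
#' @param area surface area
#' @param volume enclosed volume
#' @return dimensionless sphericity in (0, 1]
#' @export
reduced_volume <- function(area, volume) {
  6 * sqrt(pi) * volume / area^1.5
}

#' @describeIn mesh_area_volume surface-to-volume ratio (um^-1), reported at
#'   two decimals in the cell presets
#' @export
surface_to_volume <- function(m) {
  av <- mesh_area_volume(m)
  unname(av["area"] / av["volume"])
}
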