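#' Export particle frames and meshes
#'
#' Plain-text writers for common visualisation formats: XYZ trajectories,
#' legacy-VTK polydata (points or triangulated surfaces) and OFF meshes.
#'
#' @param pos n x 3 position matrix
#' @param type particle type codes or names
#' @param path output file
#' @param append append as an additional XYZ frame
#' @return the path, invisibly
#' @export
write_xyz <- function(pos, type, path, append = FALSE) {
  type <- rep_len(type, nrow(pos))
  lab <- if (is.character(type)) type else {
    names(PARTICLE_TYPES)[match(type, PARTICLE_TYPES)]
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), "frame"), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", lab, pos[, 1], pos[, 2], pos[, 3]),
             con)
  invisible(path)
}

#' @rdname write_xyz
#' @param mesh a `triangulated_membrane` (or list with `vertices`, `faces`);
#'   when `NULL`, `pos` is written as a point cloud
#' @export
write_vtk_polydata <- function(path, mesh = NULL, pos = NULL) {
  if (is.null(mesh) && is.null(pos)) stop("need a mesh or points")
  V <- if (is.null(mesh)) as.matrix(pos) else mesh$vertices
  lines <- c("# vtk DataFile Version 3.0", "mavessel export", "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d float", nrow(V)),
             sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]))
  if (!is.null(mesh)) {
    F <- mesh$faces
    lines <- c(lines,
               sprintf("POLYGONS %d %d", nrow(F), 4 * nrow(F)),
               sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1))
  } else {
    lines <- c(lines,
               sprintf("VERTICES %d %d", nrow(V), 2 * nrow(V)),
               sprintf("1 %d", seq_len(nrow(V)) - 1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_off <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  writeLines(c("OFF",
               sprintf("%d %d %d", nrow(V), nrow(F), 0),
               sprintf("%.8f %.8f %.8f", V[, 1], V[, 2], V[, 3]),
               sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1)),
             path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  V <- do.call(rbind, lapply(ln[2 + seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  F <- do.call(rbind, lapply(ln[2 + nv + seq_len(nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 3) stop("only triangle faces supported")
    v[2:4] + 1L
  }))
  m <- structure(list(vertices = V, faces = F),
                 class = "triangulated_membrane")
  m$edges <- mesh_edges(F)
  m$dihedrals <- mesh_dihedrals(F)
  m$l0 <- sqrt(rowSums((V[m$edges[, 1], ] - V[m$edges[, 2], ])^2))
  m$theta0 <- mesh_dihedral_angles(m)
  av <- mesh_area_volume(m)
  m$area <- av["area"]
  m$volume <- av["volume"]
  m
}

#' Write cell tracks as a plain-text table
#'
#' @param tracks tracks data frame from [run_simulation()]
#' @param path output TSV path
#' @export
write_tracks <- function(tracks, path) {
  write.table(tracks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
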