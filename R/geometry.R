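## Spherical membrane geometry: sphere meshes, compartment coupling, geodesics.

#' Convert cell volume to sphere radius
#'
#' Cells are approximated as spheres; volumes are given in femtolitres
#' (1 fL = 1 um^3) throughout.
#'
#' @param volume Cell volume in fL (um^3). Must be positive.
#' @return Radius in um, `(3 V / 4 pi)^(1/3)`.
#' @examples
#' volume_to_radius(4 / 3 * pi) # unit sphere
#' volume_to_radius(65)
#' @export
volume_to_radius <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("`volume` must be positive and finite", call. = FALSE)
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Convert sphere radius to cell volume
#'
#' @param radius Sphere radius in um.
#' @return Volume in fL (um^3).
#' @export
radius_to_volume <- function(radius) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("`radius` must be positive and finite", call. = FALSE)
  4 / 3 * pi * radius^3
}

#' Membrane-to-cytosol volume ratio
#'
#' The membrane is treated as a thin spherical shell of thickness `R_m` on a
#' cell of radius `R`; the ratio of shell volume to cytosolic volume is
#' `eta = ((R + R_m)^3 - R^3) / R^3`. `eta` converts surface reaction fluxes
#' (per membrane-compartment volume) into cytosolic concentration changes.
#'
#' @param R Cell radius in um (> 0).
#' @param R_m Membrane thickness in um (>= 0, default 0.01 = 10 nm).
#' @return Dimensionless ratio `eta`.
#' @examples
#' membrane_cytosol_ratio(2.5)      # ~0.012
#' membrane_cytosol_ratio(1, 1)     # (2^3 - 1)/1 = 7
#' @export
membrane_cytosol_ratio <- function(R, R_m = 0.01) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  if (any(R_m < 0)) stop("`R_m` must be non-negative", call. = FALSE)
  ((R + R_m)^3 - R^3) / R^3
}

#' Compartment geometry of a spherical cell
#'
#' Bundles the radius, membrane thickness, membrane/cytosol volume ratio and
#' cell volume used by the bulk-surface coupling.
#'
#' @param volume Cell volume in fL; exactly one of `volume`/`R` must be given.
#' @param R Cell radius in um.
#' @param R_m Membrane thickness in um (default 0.01).
#' @return An object of class `compartment_geometry` with fields `R`, `R_m`,
#'   `eta`, `volume`.
#' @export
compartment_geometry <- function(volume = NULL, R = NULL, R_m = 0.01) {
  if (is.null(R) == is.null(volume))
    stop("give exactly one of `volume` or `R`", call. = FALSE)
  if (is.null(R)) R <- volume_to_radius(volume)
  if (is.null(volume)) volume <- radius_to_volume(R)
  structure(
    list(R = R, R_m = R_m, eta = membrane_cytosol_ratio(R, R_m), volume = volume),
    class = "compartment_geometry"
  )
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("compartment_geometry: R = %.4g um, V = %.4g fL, R_m = %.3g um, eta = %.5g\n",
              x$R, x$volume, x$R_m, x$eta))
  invisible(x)
}

## ---- icosphere construction ----------------------------------------------

# Unit icosahedron (12 vertices, 20 faces), counter-clockwise orientation.
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

# One midpoint-subdivision step, vectorised over edges.
.subdivide <- function(v, f) {
  nv <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- !duplicated(key)
  idx <- match(key, key[uk])             # edge -> new-vertex index (1-based)
  mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE])
  mids <- mids / sqrt(rowSums(mids^2))
  nf <- nrow(f)
  m12 <- nv + idx[seq_len(nf)]
  m23 <- nv + idx[nf + seq_len(nf)]
  m31 <- nv + idx[2 * nf + seq_len(nf)]
  f2 <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31)
  )
  list(v = rbind(v, mids), f = f2)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build a triangulated sphere mesh
#'
#' Constructs an icosphere (recursively subdivided icosahedron projected onto
#' the sphere) of radius `R`. Available node counts are
#' `10 * 4^s + 2` for subdivision level `s` (12, 42, 162, 642, 2562, 10242,
#' 40962, ...); the level closest to `target_nodes` is chosen.
#' Lumped node areas (one third of each adjacent triangle) are the quadrature
#' weights used for all surface integrals.
#'
#' @param R Sphere radius in um.
#' @param target_nodes Desired number of mesh nodes (>= 12).
#' @param strict If `TRUE` (default), error when no subdivision level lies
#'   within 20 percent of `target_nodes`; with `FALSE` the closest level is
#'   used.
#' @return An object of class `surface_mesh`: `nodes` (N x 3, um),
#'   `triangles` (F x 3 indices), `node_area` (N, um^2), `R`, `A_m` (um^2).
#' @examples
#' m <- build_sphere_mesh(2.5, 642)
#' abs(sum(m$node_area) - 4 * pi * 2.5^2) / (4 * pi * 2.5^2) # below 0.01
#' @export
build_sphere_mesh <- function(R, target_nodes = 2562, strict = TRUE) {
  if (!is.finite(R) || R <= 0) stop("`R` must be positive", call. = FALSE)
  if (target_nodes < 12) stop("`target_nodes` must be >= 12", call. = FALSE)
  levels <- 0:8
  counts <- 10 * 4^levels + 2
  s <- levels[which.min(abs(counts - target_nodes))]
  got <- 10 * 4^s + 2
  if (strict && abs(got - target_nodes) / target_nodes > 0.2)
    stop(sprintf(paste0(
      "cannot mesh sphere (R = %g) within 20%% of target_nodes = %d: ",
      "icosphere node counts are %s; closest is %d. ",
      "Use strict = FALSE to accept the closest count."),
      R, target_nodes, paste(counts[1:7], collapse = ", "), got), call. = FALSE)
  ic <- .icosahedron()
  v <- ic$v; f <- ic$f
  if (s > 0) for (i in seq_len(s)) {
    sub <- .subdivide(v, f); v <- sub$v; f <- sub$f
  }
  nodes <- v * R
  p1 <- nodes[f[, 1], , drop = FALSE]
  p2 <- nodes[f[, 2], , drop = FALSE]
  p3 <- nodes[f[, 3], , drop = FALSE]
  tri_area <- sqrt(rowSums(.cross3(p2 - p1, p3 - p1)^2)) / 2
  node_area <- as.numeric(rowsum(rep(tri_area / 3, 3L),
                                 c(f[, 1], f[, 2], f[, 3]), reorder = TRUE))
  structure(
    list(nodes = nodes, triangles = f, node_area = node_area,
         R = R, A_m = sum(tri_area), n_nodes = nrow(nodes)),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d triangles, R = %.4g um, area = %.4g um^2\n",
              x$n_nodes, nrow(x$triangles), x$R, x$A_m))
  invisible(x)
}

#' Geodesic (great-circle) distance between mesh nodes
#'
#' @param mesh A `surface_mesh`.
#' @param node_a,node_b Node indices (vectors recycle).
#' @return Arc length(s) in um, `R * acos(x_a . x_b / R^2)`.
#' @export
geodesic_distance <- function(mesh, node_a, node_b) {
  n <- mesh$n_nodes
  if (any(node_a < 1 | node_a > n) || any(node_b < 1 | node_b > n))
    stop("node index out of bounds", call. = FALSE)
  a <- mesh$nodes[node_a, , drop = FALSE]
  b <- mesh$nodes[node_b, , drop = FALSE]
  cosang <- rowSums(a * b) / mesh$R^2
  mesh$R * acos(pmin(1, pmax(-1, cosang)))
}

# Geodesic distance from one fixed unit direction to all nodes.
.geodesic_from_point <- function(mesh, centre_unit) {
  cosang <- (mesh$nodes %*% centre_unit) / mesh$R
  as.numeric(mesh$R * acos(pmin(1, pmax(-1, cosang))))
}

# Undirected edge list (unique pairs) of the triangulation.
.mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# Euler characteristic V - E + F (2 for a closed sphere-like surface).
.euler_characteristic <- function(mesh) {
  mesh$n_nodes - nrow(.mesh_edges(mesh)) + nrow(mesh$triangles)
}

#' Export a mesh and nodal fields in legacy VTK format
#'
#' Writes an ASCII VTK PolyData file readable by ParaView for snapshot
#' visualisation.
#'
#' @param mesh A `surface_mesh`.
#' @param file Output path.
#' @param fields Named list of nodal vectors (point data).
#' @return `file`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, file, fields = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- mesh$n_nodes
  writeLines(c("# vtk DataFile Version 3.0", "septring surface mesh",
               "ASCII", "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  f <- mesh$triangles - 1L
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  write(t(cbind(3L, f)), con, ncolumns = 4)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      write(fields[[nm]], con, ncolumns = 9)
    }
  }
  invisible(file)
}
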