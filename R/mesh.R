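#' Triangulated surface mesh
#'
#' A closed triangulated surface in millimetre units, the container used for
#' pre- and post-void bladder anatomies. Vertices are an `n x 3` numeric
#' matrix, faces an `m x 3` integer matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of vertex indices (1-based).
#' @param provenance free-text label, e.g. `"pre-void"`, `"post-void"`,
#'   `"synthetic"`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, provenance = "unknown") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  if (nrow(faces) == 0L) stop("empty mesh: no faces", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3])) {
    stop("faces with repeated vertices", call. = FALSE)
  }
  structure(
    list(vertices = vertices, faces = faces, provenance = provenance),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces, provenance \"%s\">\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  invisible(x)
}

#' @export
#' @rdname surface_mesh
is_surface_mesh <- function(x) inherits(x, "surface_mesh")

# per-face vertex coordinate triples, as three n_face x 3 matrices
face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- row_cross(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' Validate a surface mesh
#'
#' Checks closedness (every edge shared by exactly two faces), consistent
#' orientation (every undirected edge traversed once in each direction), and
#' counts degenerate (near-zero-area) faces. Reports; never raises.
#'
#' @param mesh a [surface_mesh()].
#' @param area_tol faces with area below this (mm^2) count as degenerate.
#' @return A one-row tibble of class `mesh_validation` with columns `closed`,
#'   `oriented`, `degenerate_faces`, `n_vertices`, `n_faces`,
#'   `n_boundary_edges`. Serialize with [jsonlite::toJSON()].
#' @export
validate_mesh <- function(mesh, area_tol = 1e-12) {
  stopifnot(is_surface_mesh(mesh))
  f <- mesh$faces
  # directed edges of every face
  e_from <- c(f[, 1], f[, 2], f[, 3])
  e_to   <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(e_from, e_to)
  hi <- pmax(e_from, e_to)
  key <- paste(lo, hi)
  cnt <- table(key)
  closed <- all(cnt == 2L)
  n_boundary <- sum(cnt == 1L)
  # consistent orientation: each undirected edge appears once per direction
  dir_key <- paste(e_from, e_to)
  oriented <- closed && !anyDuplicated(dir_key)
  degen <- sum(face_areas(mesh) < area_tol)
  structure(
    tibble::tibble(
      closed = closed, oriented = oriented, degenerate_faces = as.integer(degen),
      n_vertices = nrow(mesh$vertices), n_faces = nrow(f),
      n_boundary_edges = as.integer(n_boundary)
    ),
    class = c("mesh_validation", class(tibble::tibble()))
  )
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by summing tetrahedra spanned by each face and the coordinate
#' origin (divergence theorem); returned positive regardless of winding.
#'
#' @param mesh a closed [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (!rep$closed) {
    stop(sprintf("mesh is not closed (%d boundary edges); volume undefined",
                 rep$n_boundary_edges), call. = FALSE)
  }
  abs(signed_mesh_volume(mesh))
}

signed_mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * row_cross(fc$b, fc$c))) / 6
}

#' Volume-weighted centroid of a closed mesh
#'
#' Centroid of the enclosed solid (not the vertex mean), via signed tetrahedra
#' against the coordinate origin.
#'
#' @inheritParams mesh_volume
#' @return Numeric length-3 point (mm).
#' @export
mesh_centroid <- function(mesh) {
  rep <- validate_mesh(mesh)
  if (!rep$closed) {
    stop(sprintf("mesh is not closed (%d boundary edges); centroid undefined",
                 rep$n_boundary_edges), call. = FALSE)
  }
  fc <- face_corners(mesh)
  vol6 <- rowSums(fc$a * row_cross(fc$b, fc$c))  # 6 * signed tet volume
  ctr <- (fc$a + fc$b + fc$c) / 4                # tet centroid (4th vertex = origin)
  v <- sum(vol6)
  as.numeric(colSums(ctr * vol6) / v)
}

#' Ensure outward orientation
#'
#' Flips all faces if the signed volume is negative (segmentation exports vary
#' in winding); identity otherwise.
#'
#' @inheritParams mesh_volume
#' @return The mesh, outward-oriented.
#' @export
orient_mesh <- function(mesh) {
  if (signed_mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Rigid and affine helpers
#'
#' @param mesh a [surface_mesh()].
#' @param offset numeric length-3 translation (mm).
#' @return The transformed mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), `+`)
  mesh
}

#' @param factor scalar scale factor.
#' @rdname translate_mesh
#' @export
scale_mesh <- function(mesh, factor) {
  mesh$vertices <- mesh$vertices * factor
  mesh
}

#' @param rotation 3x3 rotation matrix.
#' @rdname translate_mesh
#' @export
rotate_mesh <- function(mesh, rotation) {
  mesh$vertices <- mesh$vertices %*% t(rotation)
  mesh
}

#' Tidy a surface mesh into a vertex tibble
#'
#' @param x a [surface_mesh()].
#' @param ... unused.
#' @return Tibble with columns `vertex`, `x`, `y`, `z`.
#' @export
tidy.surface_mesh <- function(x, ...) {
  tibble::tibble(vertex = seq_len(nrow(x$vertices)),
                 x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3])
}

#' @export
glance.surface_mesh <- function(x, ...) {
  rep <- validate_mesh(x)
  vol <- if (rep$closed) abs(signed_mesh_volume(x)) else NA_real_
  tibble::tibble(
    n_vertices = rep$n_vertices, n_faces = rep$n_faces, closed = rep$closed,
    oriented = rep$oriented, degenerate_faces = rep$degenerate_faces,
    volume_mm3 = vol, provenance = x$provenance
  )
}
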