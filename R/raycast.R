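#' Ray-triangle intersection (Moller-Trumbore)
#'
#' The fast, minimum-storage ray-triangle intersection test used to measure
#' radial distances from the bladder-centric origin to each surface. Boundary
#' hits (barycentric coordinates within `eps` of the edge) count as hits;
#' intersections behind the ray origin do not.
#'
#' @param origin numeric length-3 ray origin (mm).
#' @param direction numeric length-3 unit direction (|d| = 1 within 1e-9).
#' @param triangle 3x3 matrix, one vertex per row (mm).
#' @param eps barycentric tolerance.
#' @return The hit distance `t >= 0` (mm), or `NA_real_` for no hit.
#'   Degenerate triangles (area < 1e-12 mm^2) return no-hit with a warning.
#' @export
ray_triangle_intersect <- function(origin, direction, triangle, eps = 1e-9) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("`direction` must be a unit vector", call. = FALSE)
  }
  triangle <- as.matrix(triangle)
  e1 <- triangle[2, ] - triangle[1, ]
  e2 <- triangle[3, ] - triangle[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (0.5 * sqrt(sum(cr^2)) < 1e-12) {
    warning("degenerate triangle (area < 1e-12 mm^2); no hit")
    return(NA_real_)
  }
  hits <- mt_cast(as.numeric(origin), direction,
                  matrix(triangle[1, ], 1), matrix(e1, 1), matrix(e2, 1),
                  eps = eps)
  if (length(hits) == 0L) NA_real_ else hits[1]
}

# Vectorized Moller-Trumbore: one ray against many triangles.
# v0, e1, e2: n x 3 matrices (first corner and edge vectors).
# Returns sorted vector of hit distances t >= 0 (possibly empty).
mt_cast <- function(origin, dir, v0, e1, e2, eps = 1e-9) {
  px <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  py <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  pz <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  det <- e1[, 1] * px + e1[, 2] * py + e1[, 3] * pz
  ok <- abs(det) > 1e-12
  tx <- origin[1] - v0[, 1]
  ty <- origin[2] - v0[, 2]
  tz <- origin[3] - v0[, 3]
  inv <- ifelse(ok, 1 / det, 0)
  u <- (tx * px + ty * py + tz * pz) * inv
  ok <- ok & u >= -eps & u <= 1 + eps
  qx <- ty * e1[, 3] - tz * e1[, 2]
  qy <- tz * e1[, 1] - tx * e1[, 3]
  qz <- tx * e1[, 2] - ty * e1[, 1]
  v <- (dir[1] * qx + dir[2] * qy + dir[3] * qz) * inv
  ok <- ok & v >= -eps & (u + v) <= 1 + eps
  tt <- (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz) * inv
  ok <- ok & tt >= -eps
  sort(pmax(tt[ok], 0))
}

# Precomputed cast structure for repeated queries against one mesh.
mesh_caster <- function(mesh) {
  fc <- face_corners(mesh)
  list(v0 = fc$a, e1 = fc$b - fc$a, e2 = fc$c - fc$a)
}

# All hit distances (deduplicated within tol: rays through shared edges or
# vertices report one crossing, not one per incident face).
cast_all_hits <- function(caster, origin, dir, dedupe_tol = 1e-7) {
  hits <- mt_cast(origin, dir, caster$v0, caster$e1, caster$e2)
  if (length(hits) <= 1L) return(hits)
  hits[c(TRUE, diff(hits) > dedupe_tol * max(1, hits[1]))]
}

#' Radial distance from an interior origin to the surface
#'
#' Casts a ray from the frame origin along a (theta, phi) direction and
#' returns the nearest surface crossing. Multiple crossings (a surface that is
#' not star-shaped about the origin) are reported via the multiplicity count.
#'
#' @param mesh a closed [surface_mesh()].
#' @param frame a [spherical_frame()] whose origin lies inside the mesh.
#' @param direction numeric length-2 `c(theta, phi)`: polar angle from the
#'   frame's +z (dome) axis and azimuth from +x (subject-left), radians.
#' @return A list with `r` (mm, nearest crossing) and `multiplicity`
#'   (number of distinct crossings along the ray).
#' @export
radial_distance <- function(mesh, frame, direction) {
  stopifnot(is_surface_mesh(mesh), inherits(frame, "spherical_frame"))
  d_world <- frame_direction(frame, direction[1], direction[2])
  hits <- cast_all_hits(mesh_caster(mesh), frame$origin, d_world)
  if (length(hits) == 0L) {
    stop(sprintf("ray (theta=%.4f, phi=%.4f) does not intersect the mesh",
                 direction[1], direction[2]), call. = FALSE)
  }
  list(r = hits[1], multiplicity = length(hits))
}
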