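#' Bladder-centric spherical coordinate frame
#'
#' The spherical coordinate system of the radial wall-motion model: origin at
#' the volume centroid of the post-void bladder, axes a right-handed
#' orthonormal triad (+x subject-left, +y anterior, +z dome/superior).
#' Anatomical orientation is lost in STL export, so for real data the axes are
#' a required user input; synthetic fixtures use the canonical identity axes.
#'
#' @param origin numeric length-3 origin (mm).
#' @param axes 3x3 matrix whose columns are the x, y, z unit axes.
#' @return An object of class `spherical_frame`.
#' @export
spherical_frame <- function(origin, axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9) {
    stop("`axes` must be orthonormal within 1e-9", call. = FALSE)
  }
  if (det(axes) < 0) stop("`axes` must be right-handed", call. = FALSE)
  structure(list(origin = origin, axes = axes), class = "spherical_frame")
}

#' @export
print.spherical_frame <- function(x, ...) {
  cat(sprintf("<spherical_frame: origin (%.3f, %.3f, %.3f) mm>\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Frame anchored at the post-void volume centroid
#'
#' @param post_mesh the post-void [surface_mesh()].
#' @param axes orthonormal axes (columns x, y, z); identity by default.
#' @return A [spherical_frame()].
#' @export
frame_from_post_void <- function(post_mesh, axes = diag(3)) {
  spherical_frame(mesh_centroid(post_mesh), axes)
}

# world-space unit direction for spherical angles in the frame
frame_direction <- function(frame, theta, phi) {
  local <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  as.numeric(frame$axes %*% local)
}

# world n x 3 matrix of directions for vectors of angles
frame_directions <- function(frame, theta, phi) {
  local <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  local %*% t(frame$axes)
}

# spherical angles (theta from +z, phi from +x) of world directions (n x 3)
frame_angles <- function(frame, dirs_world) {
  local <- dirs_world %*% frame$axes
  list(theta = acos(pmin(1, pmax(-1, local[, 3]))),
       phi = atan2(local[, 2], local[, 1]),
       local = local)
}

#' Point-in-mesh test by ray parity
#'
#' @param mesh a closed [surface_mesh()].
#' @param point numeric length-3 point (mm).
#' @return `TRUE` if the point lies inside the mesh.
#' @export
point_in_mesh <- function(mesh, point) {
  caster <- mesh_caster(mesh)
  # slightly irrational direction avoids edge-parallel degeneracies
  dir <- c(0.5812381937190965, 0.3876254624793977, 0.7155417527999327)
  hits <- cast_all_hits(caster, as.numeric(point), dir)
  (length(hits) %% 2L) == 1L
}
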