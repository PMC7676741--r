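#' Planar cross-section contour of a mesh, in radial form
#'
#' Cuts a closed mesh with a plane through the frame origin and returns the
#' cross-section contour as radii sampled at uniform polar angles about the
#' origin (valid because the bladder surface is star-shaped about the
#' bladder-centric origin). Plane conventions, in frame axes:
#' `"sagittal"` — normal +x (left), in-plane coordinates (a, b) =
#' (anterior, superior); `"coronal"` — normal +y (anterior), in-plane
#' (a, b) = (left, superior). In both, `b` is the superior axis, so the
#' inferior contour point (toward the bladder neck) sits at angle -pi/2.
#'
#' @param mesh a closed [surface_mesh()].
#' @param frame a [spherical_frame()].
#' @param plane `"sagittal"` or `"coronal"`.
#' @param n_psi number of uniform polar angles.
#' @return List with `psi` (angles, radians), `r` (radii, mm), `area_mm2`
#'   (polygon area) and `points` (`n_psi x 2` matrix of (a, b) coordinates).
#' @export
mesh_plane_contour <- function(mesh, frame, plane = c("sagittal", "coronal"),
                               n_psi = 256L) {
  plane <- match.arg(plane)
  ax <- switch(plane,
    sagittal = list(n = frame$axes[, 1], a = frame$axes[, 2], b = frame$axes[, 3]),
    coronal  = list(n = frame$axes[, 2], a = frame$axes[, 1], b = frame$axes[, 3])
  )
  rel <- sweep(mesh$vertices, 2, frame$origin, `-`)
  s <- as.numeric(rel %*% ax$n)
  # vertices numerically on the plane are nudged to the positive side so the
  # contour never degenerates into in-plane edges (simulation of simplicity)
  eps <- 1e-9 * max(abs(s), 1)
  s[abs(s) < eps] <- eps
  f <- mesh$faces
  sf <- cbind(s[f[, 1]], s[f[, 2]], s[f[, 3]])
  crossing <- (apply(sf, 1, max) > 0) & (apply(sf, 1, min) < 0)
  if (!any(crossing)) {
    stop("plane misses or is tangent to the mesh: no cross-section", call. = FALSE)
  }
  a_of <- as.numeric(rel %*% ax$a)
  b_of <- as.numeric(rel %*% ax$b)
  segs <- matrix(NA_real_, nrow = 0, ncol = 4)  # a1 b1 a2 b2
  seg_list <- lapply(which(crossing), function(k) {
    vi <- f[k, ]
    sv <- s[vi]
    pts <- matrix(NA_real_, 0, 2)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      s1 <- sv[e[1]]
      s2 <- sv[e[2]]
      if ((s1 > 0) != (s2 > 0)) {
        w <- s1 / (s1 - s2)
        i1 <- vi[e[1]]
        i2 <- vi[e[2]]
        pts <- rbind(pts, c(a_of[i1] + w * (a_of[i2] - a_of[i1]),
                            b_of[i1] + w * (b_of[i2] - b_of[i1])))
      }
    }
    if (nrow(pts) == 2) c(pts[1, ], pts[2, ]) else NULL
  })
  segs <- do.call(rbind, Filter(Negate(is.null), seg_list))
  psi <- seq(-pi, pi, length.out = n_psi + 1L)[seq_len(n_psi)]
  r <- radial_sample_segments(segs, psi)
  if (anyNA(r)) {
    stop("contour not star-shaped about the origin in the cut plane (",
         sum(is.na(r)), " rays unmatched)", call. = FALSE)
  }
  pts <- cbind(r * cos(psi), r * sin(psi))
  list(psi = psi, r = r, area_mm2 = polygon_area(pts), points = pts)
}

# nearest positive ray-segment intersection distance per angle (NA if none)
radial_sample_segments <- function(segs, psi) {
  p1a <- segs[, 1]; p1b <- segs[, 2]
  ea <- segs[, 3] - p1a; eb <- segs[, 4] - p1b
  vapply(psi, function(ps) {
    da <- cos(ps); db <- sin(ps)
    denom <- da * eb - db * ea
    ok <- abs(denom) > 1e-14
    tt <- (p1a * eb - p1b * ea) / denom
    uu <- (p1a * db - p1b * da) / denom
    ok <- ok & uu >= -1e-9 & uu <= 1 + 1e-9 & tt > 0
    if (!any(ok)) NA_real_ else min(tt[ok])
  }, numeric(1))
}

# shoelace area of a closed polygon given as an n x 2 matrix
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
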