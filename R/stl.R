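#' Read an STL surface file
#'
#' Reads binary or ASCII stereolithography files (the export format of most
#' segmentation software). STL stores each facet independently; duplicate
#' vertices are welded at a 1e-6 mm grid so downstream edge-topology checks
#' see shared vertices. Coordinates are interpreted as millimetres (STL has no
#' unit metadata); rescale with [scale_mesh()] if your export used other units.
#'
#' @param path file path.
#' @param provenance label recorded on the mesh; defaults to the file name.
#' @param weld_tol vertex welding tolerance (mm).
#' @return A [surface_mesh()] whose face count equals the STL facet count.
#' @export
read_stl <- function(path, provenance = basename(path), weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("not a readable STL file: ", path, call. = FALSE)
  tri <- if (is_binary_stl(path, sz)) read_stl_binary(path, sz) else read_stl_ascii(path)
  if (nrow(tri) == 0L) stop("STL file contains zero facets: ", path, call. = FALSE)
  weld_triangle_soup(tri, provenance = provenance, tol = weld_tol)
}

# Heuristic: binary iff the 84-byte header's facet count matches the file size.
is_binary_stl <- function(path, sz) {
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  !is.na(n) && n >= 0 && sz == 84 + 50 * as.numeric(n)
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", n = 50 * n)
  if (length(raw) < 50 * n) stop("truncated binary STL: ", path, call. = FALSE)
  m <- matrix(raw, nrow = 50)                         # one facet per column
  flt <- readBin(as.vector(m[1:48, , drop = FALSE]), "double",
                 n = 12L * n, size = 4, endian = "little")
  rec <- matrix(flt, nrow = 12)                       # nrm(3), v1, v2, v3
  t(rec[4:12, , drop = FALSE])                        # n x 9: v1 v2 v3
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L) return(matrix(numeric(0), ncol = 9))
  if (length(vl) %% 3 != 0) stop("truncated ASCII STL: ", path, call. = FALSE)
  num <- scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE)
  v <- matrix(num, ncol = 3, byrow = TRUE)
  n <- nrow(v) / 3
  cbind(v[3 * seq_len(n) - 2, , drop = FALSE],
        v[3 * seq_len(n) - 1, , drop = FALSE],
        v[3 * seq_len(n), , drop = FALSE])
}

# tri: n x 9 matrix of facet corner coordinates -> welded surface_mesh
weld_triangle_soup <- function(tri, provenance, tol = 1e-6) {
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol), round(pts[, 3] / tol))
  vmap <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  n <- nrow(tri)
  faces <- cbind(vmap[seq_len(n)], vmap[n + seq_len(n)], vmap[2 * n + seq_len(n)])
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  if (!all(keep)) {
    warning(sum(!keep), " facet(s) collapsed under vertex welding; dropped")
    faces <- faces[keep, , drop = FALSE]
  }
  orient_mesh(surface_mesh(verts, faces, provenance = provenance))
}

#' Write a binary STL file
#'
#' Writes a fixed 80-byte header (no timestamp, so identical meshes produce
#' identical bytes). The mesh must validate as closed, oriented and
#' non-degenerate.
#'
#' @param mesh a [surface_mesh()] passing [validate_mesh()].
#' @param path output path.
#' @param check if `TRUE` (default) refuse meshes that fail validation.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, check = TRUE) {
  stopifnot(is_surface_mesh(mesh))
  if (check) {
    rep <- validate_mesh(mesh)
    if (!rep$closed || !rep$oriented || rep$degenerate_faces > 0) {
      stop("mesh fails validation (closed=", rep$closed, ", oriented=",
           rep$oriented, ", degenerate=", rep$degenerate_faces,
           "); pass check = FALSE to force", call. = FALSE)
    }
  }
  fc <- face_corners(mesh)
  nrm <- row_cross(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, .Machine$double.eps)
  n <- nrow(mesh$faces)
  rec <- t(cbind(nrm, fc$a, fc$b, fc$c))    # 12 floats per facet
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "vesica binary STL (mm)"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  flt <- writeBin(as.vector(rec), raw(), size = 4, endian = "little")
  fm <- matrix(flt, nrow = 48)
  attr_bytes <- as.raw(c(0, 0))
  body <- rbind(fm, matrix(rep(attr_bytes, n), nrow = 2))
  writeBin(as.vector(body), con)
  invisible(path)
}
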