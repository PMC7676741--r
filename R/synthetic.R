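#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere — the base shape for
#' synthetic bladder fixtures. Star-shaped about its centre by construction,
#' which is the validity domain of the radial displacement model.
#'
#' @param radius sphere radius (mm), > 0.
#' @param subdivisions integer 0..6; vertex count is `10 * 4^s + 2`.
#' @param center numeric length-3 centre (mm).
#' @return A [surface_mesh()].
#' @export
make_sphere_mesh <- function(radius, subdivisions = 3L, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0, subdivisions <= 6)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    res <- subdivide_tri(v, f)
    v <- res$v
    f <- res$f
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, as.numeric(center), `+`)
  orient_mesh(surface_mesh(v, f, provenance = "synthetic"))
}

# one loop-subdivision split (no smoothing): each face -> 4, midpoints welded
subdivide_tri <- function(v, f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  mid_id <- match(key, key[first]) + nrow(v)
  mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
  n <- nrow(f)
  m12 <- mid_id[seq_len(n)]
  m23 <- mid_id[n + seq_len(n)]
  m31 <- mid_id[2 * n + seq_len(n)]
  list(
    v = rbind(v, mids),
    f = rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  )
}

#' Voiding scenario specification
#'
#' Parameters of a synthetic pre/post-void mesh pair with an analytically
#' known radial displacement field. Patterns: `uniform` (equal displacement
#' everywhere), `dome_weighted` (extra displacement toward the dome apex, the
#' pattern seen in healthy voiding), `asymmetric` (left hemisphere scaled by
#' `asym_gain`, blended over a 10 degree band at the midplane — the impaired,
#' lateralized pattern).
#'
#' @param pattern one of `"uniform"`, `"dome_weighted"`, `"asymmetric"`.
#' @param r_pre pre-void mean radius (mm).
#' @param shrink_fraction fraction of radius lost over voiding, in (0, 1).
#' @param dome_gain multiplicative extra displacement at the dome apex (>= 1).
#' @param asym_gain left-over-right displacement ratio (> 0).
#' @param mesh_subdivisions icosphere subdivisions for both meshes.
#' @param seed integer seed for any stochastic extras.
#' @return A list of class `voiding_scenario`.
#' @export
voiding_scenario <- function(pattern = c("uniform", "dome_weighted", "asymmetric"),
                             r_pre = 40, shrink_fraction = 1 / 3,
                             dome_gain = 2, asym_gain = 1.5,
                             mesh_subdivisions = 4L, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(r_pre > 0, shrink_fraction > 0, shrink_fraction < 1,
            dome_gain >= 1, asym_gain > 0,
            mesh_subdivisions >= 0, mesh_subdivisions <= 6)
  structure(list(pattern = pattern, r_pre = r_pre,
                 shrink_fraction = shrink_fraction, dome_gain = dome_gain,
                 asym_gain = asym_gain, mesh_subdivisions = as.integer(mesh_subdivisions),
                 seed = as.integer(seed)),
            class = "voiding_scenario")
}

# analytic ground-truth total radial displacement at unit directions (n x 3)
scenario_d0 <- function(scenario, dirs) {
  base <- scenario$shrink_fraction * scenario$r_pre
  gain <- switch(scenario$pattern,
    uniform = rep(1, nrow(dirs)),
    dome_weighted = 1 + (scenario$dome_gain - 1) * pmax(0, dirs[, 3]),
    asymmetric = asym_blend_gain(dirs[, 1], scenario$asym_gain)
  )
  base * gain
}

# smooth cosine blend across a 10-degree band centred on the x = 0 midplane:
# gain = asym_gain for elevation >= +5deg (left), 1 for <= -5deg (right)
asym_blend_gain <- function(x_component, asym_gain) {
  half_band <- 5 * pi / 180
  elev <- asin(pmin(1, pmax(-1, x_component)))
  s <- (elev + half_band) / (2 * half_band)
  s <- pmin(1, pmax(0, s))
  w <- (1 - cos(pi * s)) / 2
  1 + (asym_gain - 1) * w
}

#' Synthetic pre/post-void mesh pair with ground truth
#'
#' Builds an icosphere pre-void surface and moves every vertex radially inward
#' by the scenario's analytic displacement field to form the post-void
#' surface, so the imposed field is known exactly at every direction.
#'
#' @param scenario a [voiding_scenario()].
#' @return List with elements `pre`, `post` ([surface_mesh()]s) and `truth`, a
#'   list holding `d0_true` (function of an `n x 3` direction matrix, mm),
#'   `median_left_true`, `median_right_true` (mm) and `asymmetry_true` (%),
#'   evaluated at the pre-void vertex directions.
#' @export
make_voiding_pair <- function(scenario) {
  stopifnot(inherits(scenario, "voiding_scenario"))
  pre <- make_sphere_mesh(scenario$r_pre, scenario$mesh_subdivisions)
  pre$provenance <- "pre-void"
  dirs <- pre$vertices / sqrt(rowSums(pre$vertices^2))
  d0 <- scenario_d0(scenario, dirs)
  r_post <- scenario$r_pre - d0
  if (any(r_post <= 0)) {
    stop("scenario drives post-void radius <= 0; reduce shrink_fraction or gains",
         call. = FALSE)
  }
  post <- pre
  post$vertices <- dirs * r_post
  post$provenance <- "post-void"
  left <- dirs[, 1] > 0
  truth <- list(
    d0_true = function(d) scenario_d0(scenario, d),
    median_left_true = median(d0[left]),
    median_right_true = median(d0[!left]),
    asymmetry_true = asymmetry_ratio(median(d0[left]), median(d0[!left]))
  )
  list(pre = pre, post = post, truth = truth)
}

#' Synthetic sigmoidal bladder-area curve
#'
#' Real-time-imaging bladder cross-sectional area over a voiding event. The
#' noiseless curve is `A(t) = A0 + (Aend - A0) * alpha_ref(t)^2` with
#' `alpha_ref` the square-root-of-cosine time dependence
#' ([alpha_sqrt_cosine()]), so that the area-ratio square root recovers
#' `alpha_ref` exactly. Optional i.i.d. Gaussian noise.
#'
#' @param t0,tend start/end of voiding (s), `tend > t0`.
#' @param A0,Aend pre-/post-void areas (mm^2), `A0 > Aend >= 0`.
#' @param n_samples number of samples (>= 8) on a uniform grid over
#'   `[t0 - pad, tend + pad]`.
#' @param noise_sd Gaussian noise standard deviation (mm^2).
#' @param pad quiet time (s) kept before `t0` and after `tend`.
#' @param seed integer seed used when `noise_sd > 0`.
#' @return Tibble with columns `time_s`, `area_mm2`.
#' @export
make_area_curve <- function(t0, tend, A0, Aend, n_samples = 64L,
                            noise_sd = 0, pad = 0, seed = 1L) {
  stopifnot(tend > t0, A0 > Aend, Aend >= 0, n_samples >= 8, pad >= 0,
            noise_sd >= 0)
  t <- seq(t0 - pad, tend + pad, length.out = n_samples)
  a <- alpha_sqrt_cosine(t, t0, tend, warn = FALSE)
  A <- A0 + (Aend - A0) * a^2
  if (noise_sd > 0) {
    A <- A + withr::with_seed(seed, stats::rnorm(n_samples, 0, noise_sd))
  }
  tibble::tibble(time_s = t, area_mm2 = A)
}

#' Write a synthetic fixture bundle
#'
#' Writes the STL pair, a JSON ground-truth sidecar and an area-curve CSV for
#' a scenario — the on-disk form consumed by the pipeline entry points.
#'
#' @param scenario a [voiding_scenario()].
#' @param dir output directory (created if missing).
#' @param t0,tend,n_samples,noise_sd area-curve parameters; areas are taken
#'   from the scenario's mid-sagittal pre/post disc areas.
#' @return Invisibly, a named list of the file paths written.
#' @export
synth_fixture <- function(scenario, dir, t0 = 10, tend = 40, n_samples = 64L,
                          noise_sd = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pair <- make_voiding_pair(scenario)
  paths <- list(
    pre = file.path(dir, "pre_void.stl"),
    post = file.path(dir, "post_void.stl"),
    area = file.path(dir, "area_curve.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_stl(pair$pre, paths$pre)
  write_stl(pair$post, paths$post)
  A0 <- pi * scenario$r_pre^2
  Aend <- pi * (scenario$r_pre * (1 - scenario$shrink_fraction))^2
  curve <- make_area_curve(t0, tend, A0, Aend, n_samples = n_samples,
                           noise_sd = noise_sd, seed = scenario$seed)
  write.csv(curve, paths$area, row.names = FALSE)
  truth <- list(
    pattern = scenario$pattern, r_pre_mm = scenario$r_pre,
    shrink_fraction = scenario$shrink_fraction,
    dome_gain = scenario$dome_gain, asym_gain = scenario$asym_gain,
    median_left_true_mm = pair$truth$median_left_true,
    median_right_true_mm = pair$truth$median_right_true,
    asymmetry_true_pct = pair$truth$asymmetry_true,
    t0_s = t0, tend_s = tend
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
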