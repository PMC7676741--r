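# shared fixtures, built in code and memoised per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# axis-aligned cube [0, s]^3 as 12 outward-oriented triangles
make_cube_mesh <- function(s = 2) {
  v <- as.matrix(expand.grid(x = c(0, s), y = c(0, s), z = c(0, s)))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = s (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = s (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6)    # x = s (+x)
  )
  orient_mesh(surface_mesh(v, f, provenance = "cube"))
}

ascii_stl_text <- function(mesh) {
  fc <- mesh$faces
  v <- mesh$vertices
  lines <- c("solid fixture")
  for (k in seq_len(nrow(fc))) {
    tri <- v[fc[k, ], , drop = FALSE]
    lines <- c(lines,
               " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
               "  endloop", " endfacet")
  }
  c(lines, "endsolid fixture")
}

# concentric spheres with deliberately unaligned tessellations (the post
# sphere is rotated, so sample rays hit triangle interiors, exposing the
# chordal discretization error that vanishes with refinement)
concentric_field <- function(subdiv = 4L) {
  cached(paste0("conc", subdiv), {
    pre <- make_sphere_mesh(30, subdiv)
    post <- rotate_mesh(make_sphere_mesh(20, subdiv),
                        rotation_matrix(c(1, 1, 0), 0.35))
    compute_displacement_field(pre, post, spherical_frame(c(0, 0, 0)))
  })
}

# independent brute-force intersector: solve the 3x3 linear system
# [-d | e1 | e2] (t, u, v)' = o - v0, then test barycentric containment
brute_force_intersect <- function(origin, dir, tri, eps = 1e-9) {
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  A <- cbind(-dir, e1, e2)
  if (abs(det(A)) < 1e-12) return(NA_real_)
  sol <- solve(A, origin - tri[1, ])
  t <- sol[1]
  u <- sol[2]
  v <- sol[3]
  if (u >= -eps && v >= -eps && u + v <= 1 + eps && t >= -eps) max(t, 0) else NA_real_
}

scenario_field <- function(pattern, ...) {
  key <- paste0("scen_", pattern, "_", paste(unlist(list(...)), collapse = "_"))
  cached(key, {
    sc <- voiding_scenario(pattern, ...)
    pair <- make_voiding_pair(sc)
    list(pair = pair,
         field = compute_displacement_field(pair$pre, pair$post))
  })
}

# raised-cosine alpha curve on a uniform grid
canonical_alpha <- function(t0, tend, n = 64L) {
  tg <- seq(t0, tend, length.out = n)
  tibble::tibble(time_s = tg, alpha = alpha_sqrt_cosine(tg, t0, tend, warn = FALSE))
}

# small voiding flow run reused across flow tests (uniform shrink, sagittal)
small_flow_solution <- function() {
  cached("small_flow", {
    sc <- voiding_scenario("uniform", r_pre = 15, shrink_fraction = 1 / 3,
                           mesh_subdivisions = 3)
    pair <- make_voiding_pair(sc)
    f <- compute_displacement_field(pair$pre, pair$post)
    kin <- volume_and_flow(pair$pre, f, alpha_curve = canonical_alpha(0, 20, 33),
                           keep_meshes = TRUE)
    dom <- build_domain(kin, plane = "sagittal", urethra = c(D = 6, L = 15))
    list(pair = pair, field = f, kin = kin, dom = dom,
         sol = solve_voiding_flow(dom, grid_h = 6 / 8))
  })
}

# fake one-snapshot flow solution around prescribed cell-centred fields,
# for testing the field-level metrics in isolation
synthetic_snapshot_solution <- function(u, v, h, fluid = NULL, bladder = NULL,
                                        outlet_point = c(0, 0)) {
  nx <- nrow(u)
  ny <- ncol(u)
  if (is.null(fluid)) fluid <- matrix(TRUE, nx, ny)
  if (is.null(bladder)) bladder <- fluid
  structure(list(
    h = h,
    xc = (seq_len(nx) - (nx + 1) / 2) * h,
    yc = (seq_len(ny) - (ny + 1) / 2) * h,
    times = c(0, 1),
    snapshots = rep(list(list(time_s = 0, u = u, v = v,
                              p = matrix(0, nx, ny), fluid = fluid,
                              bladder = bladder, outlet_point = outlet_point)), 2),
    diagnostics = tibble::tibble(time_s = 1, dt_s = 1, max_div_rel = 0,
                                 outlet_flux_mm2_s = 1, wall_influx_mm2_s = 1,
                                 area_mm2 = 1, dAdt_mm2_s = -1),
    D = 1, L = 1, nu = 0.7, t0 = 0, tend = 1
  ), class = "flow_solution")
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
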