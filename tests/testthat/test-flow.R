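test_that("planar cut of a sphere is a circle with the right area", {
  m <- make_sphere_mesh(30, 3)
  fr <- spherical_frame(c(0, 0, 0))
  ct <- mesh_plane_contour(m, fr, "sagittal")
  expect_equal(mean(ct$r), 30, tolerance = 0.01)
  perimeter <- sum(sqrt(rowSums((ct$points -
    ct$points[c(2:nrow(ct$points), 1), ])^2)))
  expect_equal(perimeter, 2 * pi * 30, tolerance = 0.005)
  expect_equal(ct$area_mm2, pi * 900, tolerance = 0.01)
})

test_that("a plane missing the mesh is rejected", {
  m <- make_sphere_mesh(5, 2, center = c(40, 0, 0))
  fr <- spherical_frame(c(0, 0, 0))
  expect_error(mesh_plane_contour(m, fr, "sagittal"), "misses|tangent")
})

test_that("domain construction validates the channel", {
  sfl <- small_flow_solution()
  expect_error(build_domain(sfl$kin, urethra = c(D = 40, L = 10)),
               "neck width")
  kin_nomesh <- sfl$kin
  kin_nomesh$mesh <- NULL
  expect_error(build_domain(kin_nomesh), "keep_meshes")
  dom <- sfl$dom
  expect_equal(dom$area_mm2[1], pi * 225, tolerance = 0.02)
  expect_lt(dom$area_mm2[length(dom$area_mm2)], dom$area_mm2[1])
})

test_that("under-resolved channels are refused with a suggestion", {
  expect_error(solve_voiding_flow(small_flow_solution()$dom, grid_h = 2),
               "grid_h")
})

test_that("channel Poiseuille profile matches the analytic solution", {
  cf <- solve_channel_flow(D = 5, L = 20, nu = 0.7, dp = 50, n_across = 16)
  expect_true(cf$converged)
  expect_lt(abs(cf$v_max - cf$v_max_analytic) / cf$v_max_analytic, 0.02)
  expect_lt(cf$max_div_rel, 1e-6)
})

test_that("Poiseuille error decreases monotonically with resolution", {
  errs <- vapply(c(8L, 16L, 32L), function(n) {
    solve_channel_flow(D = 5, L = 20, nu = 0.7, dp = 50, n_across = n,
                       tol = 1e-9)$profile_error_rel
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("static walls keep the fluid at rest", {
  sfl <- small_flow_solution()
  pre <- sfl$pair$pre
  flat <- tibble::tibble(time_s = c(0, 5, 10), alpha = rep(0, 3))
  kin <- volume_and_flow(pre, sfl$field, alpha_curve = flat, keep_meshes = TRUE)
  dom <- build_domain(kin, urethra = c(D = 6, L = 15))
  sol <- solve_voiding_flow(dom, grid_h = 6 / 8, n_snapshots = 3)
  for (s in sol$snapshots) {
    expect_lt(max(abs(s$u), abs(s$v), na.rm = TRUE), 1e-12)
  }
})

test_that("outlet flux balances the contour shrink rate during voiding", {
  sol <- small_flow_solution()$sol
  d <- sol$diagnostics
  err <- abs(d$outlet_flux_mm2_s - (-d$dAdt_mm2_s)) /
    pmax(abs(d$dAdt_mm2_s), 1e-9)
  expect_lt(max(err), 0.02)
  expect_lt(max(d$max_div_rel), 1e-6)
})

test_that("vorticity operator is exact on linear fields", {
  n <- 21
  h <- 0.5
  x <- (seq_len(n) - (n + 1) / 2) * h
  X <- matrix(x, n, n)
  Y <- t(X)
  # uniform flow
  expect_equal(max(abs(vorticity_from_velocity(matrix(1, n, n),
                                               matrix(0, n, n), h)),
                   na.rm = TRUE), 0)
  # solid-body rotation: omega = 2 * Omega, exactly for central differences
  om <- vorticity_from_velocity(-3 * Y, 3 * X, h)
  expect_equal(max(abs(om - 6), na.rm = TRUE), 0, tolerance = 1e-10)
})

test_that("vorticity matches an independent wide-stencil oracle on smooth fields", {
  n <- 41
  h <- 0.25
  x <- (seq_len(n) - (n + 1) / 2) * h
  X <- matrix(x, n, n)
  Y <- t(X)
  u <- sin(X) * cos(Y)
  v <- X^2 * Y / 20
  om <- vorticity_from_velocity(u, v, h)
  # 4th-order five-point stencil as the independent oracle
  d4 <- function(M, axis) {
    sh <- function(k) if (axis == 1) vesica:::shift_mat(M, k, 0) else
      vesica:::shift_mat(M, 0, k)
    (-sh(2) + 8 * sh(1) - 8 * sh(-1) + sh(-2)) / (12 * h)
  }
  om4 <- d4(v, 1) - d4(u, 2)
  core <- 3:(n - 3)
  expect_lt(max(abs(om[core, core] - om4[core, core])), 5 * h^2)
})

test_that("mean vorticity of a solid-body rotation over a disk is 2 Omega", {
  n <- 41
  h <- 0.25
  x <- (seq_len(n) - (n + 1) / 2) * h
  X <- matrix(x, n, n)
  Y <- t(X)
  disk <- X^2 + Y^2 < 16
  sol <- synthetic_snapshot_solution(-3 * Y, 3 * X, h, bladder = disk)
  mv <- mean_vorticity(sol)
  expect_equal(mv$mean_abs_vorticity_per_s, c(6, 6), tolerance = 1e-10)
  expect_equal(attr(mv, "time_average"), 6, tolerance = 1e-10)
})

test_that("dimensionless vorticity follows the chosen normalization", {
  expect_equal(dimensionless_vorticity(10, 100, 5), 2.5)
  expect_equal(dimensionless_vorticity(0, 100, 5), 0)
  expect_error(dimensionless_vorticity(10, 0, 5), "undefined")
  # invariance under joint time rescaling
  expect_equal(dimensionless_vorticity(20, 200, 5),
               dimensionless_vorticity(10, 100, 5))
  # pseudo-3D duct mode
  expect_equal(dimensionless_vorticity(10, 100, 5, mode = "pseudo3d"),
               10 * 5 / (100 / (pi * 25 / 4)))
})

test_that("recirculation fraction separates sink flow from superposed vortices", {
  n <- 41
  h <- 0.25
  x <- (seq_len(n) - (n + 1) / 2) * h
  X <- matrix(x, n, n)
  Y <- t(X)
  outlet <- c(0, -6)
  dx <- outlet[1] - X
  dy <- outlet[2] - Y
  dn <- pmax(sqrt(dx^2 + dy^2), 1e-6)
  # pure point-sink flow: everything moves toward the outlet
  sink_sol <- synthetic_snapshot_solution(dx / dn, dy / dn, h,
                                          outlet_point = outlet)
  expect_equal(recirculation_fraction(sink_sol, 1), 0)
  # superposed ideal vortex in the upper half: evaluate the analytic fraction
  # on the prescribed composite field (no solver involved)
  vx <- ifelse(Y > 0, -Y, 0) * 3
  vy <- ifelse(Y > 0, X, 0) * 3
  u <- dx / dn + vx
  v <- dy / dn + vy
  comp_sol <- synthetic_snapshot_solution(u, v, h, outlet_point = outlet)
  sp <- sqrt(u^2 + v^2)
  expected <- mean((u * dx + v * dy)[sp > 0.01 * max(sp)] < 0)
  expect_equal(recirculation_fraction(comp_sol, 1), expected)
  expect_gt(expected, 0.05)
  # sub-threshold noise counts as quiescent
  quiet <- synthetic_snapshot_solution(matrix(0, n, n), matrix(0, n, n), h,
                                       outlet_point = outlet)
  expect_warning(rf <- recirculation_fraction(quiet, 1), "quiescent")
  expect_identical(rf, 0)
})

test_that("the voiding solver is bitwise deterministic", {
  sfl <- small_flow_solution()
  sol2 <- solve_voiding_flow(sfl$dom, grid_h = 6 / 8)
  expect_identical(flow_metrics(sfl$sol), flow_metrics(sol2))
  expect_identical(sfl$sol$diagnostics$outlet_flux_mm2_s,
                   sol2$diagnostics$outlet_flux_mm2_s)
})
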