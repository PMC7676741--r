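test_that("concentric spheres recover the uniform 10 mm displacement", {
  field <- concentric_field(4)
  expect_lt(max(abs(field$d0_mm - 10)) / 10, 0.02)
  expect_identical(attr(field, "n_failed"), 0L)
})

test_that("displacement error shrinks with mesh refinement", {
  errs <- vapply(c(2L, 3L, 4L), function(s) {
    max(abs(concentric_field(s)$d0_mm - 10)) / 10
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("identical meshes give a zero field", {
  m <- make_sphere_mesh(25, 3)
  field <- compute_displacement_field(m, m, spherical_frame(c(0, 0, 0)))
  expect_lt(max(abs(field$d0_mm)), 1e-9)
})

test_that("tangential components are identically zero (radial-only model)", {
  field <- concentric_field(3)
  expect_true(all(field$dtheta_mm == 0))
  expect_true(all(field$dphi_mm == 0))
})

test_that("synthetic patterns are recovered within mesh resolution", {
  for (pattern in c("dome_weighted", "asymmetric")) {
    sf <- scenario_field(pattern, r_pre = 30, shrink_fraction = 0.2,
                         mesh_subdivisions = 3)
    dirs <- sf$pair$pre$vertices /
      sqrt(rowSums(sf$pair$pre$vertices^2))
    truth <- sf$pair$truth$d0_true(dirs)
    edge_len <- 30 * 2 * pi / (10 * 2^3)   # mean icosphere edge scale
    expect_lt(max(abs(sf$field$d0_mm - truth)), 2 * edge_len)
  }
})

test_that("region labels follow the frame axes with deterministic ties", {
  field <- concentric_field(3)
  apex <- which.min(field$theta_rad)
  expect_identical(field$region_db[apex], "dome")
  # sign test in all three axes at (1,1,1)/sqrt(3)
  d <- c(1, 1, 1) / sqrt(3)
  th <- acos(d[3])
  ph <- atan2(d[2], d[1])
  lab <- partition_regions(tibble::tibble(theta_rad = th, phi_rad = ph, d0_mm = 1))
  expect_identical(lab$region_ap, "anterior")
  expect_identical(lab$region_db, "dome")
  expect_identical(lab$region_lr, "left")
  # boundary samples go to the positive side
  lab0 <- partition_regions(tibble::tibble(theta_rad = pi / 2, phi_rad = pi / 2,
                                           d0_mm = 1))
  expect_identical(lab0$region_lr, "left")   # x-component is +0 at phi = pi/2
  # near-uniform direction sampling puts about half the samples per side
  usamp <- compute_displacement_field(make_sphere_mesh(30, 2),
                                      make_sphere_mesh(20, 2),
                                      spherical_frame(c(0, 0, 0)),
                                      sampling = "uniform_sphere",
                                      n_samples = 2000)
  for (col in c("region_ap", "region_db", "region_lr")) {
    expect_equal(mean(usamp[[col]] %in% c("anterior", "dome", "left")), 0.5,
                 tolerance = 0.02)
  }
})

test_that("regional five-number summaries use interpolated quartiles", {
  field <- structure(
    tibble::tibble(theta_rad = rep(1, 10), phi_rad = seq(0.1, 1, 0.1),
                   d0_mm = c(1:5, 1:5),
                   region_ap = rep(c("anterior", "posterior"), 5),
                   region_db = rep(c("dome", "base"), 5),
                   region_lr = rep(c("left", "right"), each = 5)),
    class = c("displacement_field", class(tibble::tibble())))
  st <- regional_stats(field, min_samples = 2L)
  left <- st[st$region == "left", ]       # exactly the samples {1,2,3,4,5}
  expect_equal(left$median, 3)
  expect_equal(left$q1, 2)
  expect_equal(left$q3, 4)
  expect_equal(left$min, 1)
  expect_equal(left$max, 5)
  expect_error(regional_stats(field, min_samples = 6L), "fewer than")
})

test_that("uniform scenario yields flat regional statistics", {
  field <- scenario_field("uniform", r_pre = 30, shrink_fraction = 1 / 3,
                          mesh_subdivisions = 3)$field
  st <- regional_stats(field)
  expect_equal(st$median, rep(10, 6), tolerance = 1e-9)
  expect_lt(max(st$q3 - st$q1), 1e-9)
  expect_lt(attr(st, "asymmetry_pct"), 1e-9)
})

test_that("asymmetric scenario medians match the imposed gains", {
  sf <- scenario_field("asymmetric", r_pre = 30, shrink_fraction = 1 / 3,
                       asym_gain = 1.5, mesh_subdivisions = 4)
  st <- regional_stats(sf$field)
  expect_equal(st$median[st$region == "left"], 15, tolerance = 0.02)
  expect_equal(st$median[st$region == "right"], 10, tolerance = 0.02)
  expect_equal(attr(st, "asymmetry_pct"), 40, tolerance = 0.05 * 40)
})

test_that("asymmetry ratio formula and its edge cases", {
  expect_equal(asymmetry_ratio(10, 10), 0)
  expect_equal(asymmetry_ratio(15, 10), 40)
  expect_equal(asymmetry_ratio(10, 2), 400 / 3, tolerance = 1e-9)
  expect_gt(asymmetry_ratio(10, 1), 100)   # normalization admits > 100%
  expect_error(asymmetry_ratio(0, 0), "undefined")
})

test_that("rigid rotation of meshes and frame leaves the field unchanged", {
  Rm <- rotation_matrix(c(1, 2, 3), 0.7)
  pre <- make_sphere_mesh(30, 3)
  post0 <- scenario_field("dome_weighted", r_pre = 30, shrink_fraction = 0.2,
                          mesh_subdivisions = 3)$pair$post
  f1 <- compute_displacement_field(pre, post0, spherical_frame(c(0, 0, 0)))
  f2 <- compute_displacement_field(rotate_mesh(pre, Rm), rotate_mesh(post0, Rm),
                                   spherical_frame(c(0, 0, 0), axes = Rm))
  expect_equal(f1$d0_mm, f2$d0_mm, tolerance = 1e-9)
  s1 <- regional_stats(f1)
  s2 <- regional_stats(f2)
  expect_equal(s1$median, s2$median, tolerance = 1e-9)
})

test_that("x-symmetric fields give near-zero asymmetry", {
  for (pattern in c("uniform", "dome_weighted")) {
    sf <- scenario_field(pattern, r_pre = 30, shrink_fraction = 0.25,
                         mesh_subdivisions = 4)
    expect_lt(attr(regional_stats(sf$field), "asymmetry_pct"), 1)
  }
})

test_that("displacement density is a proper Gaussian KDE", {
  withr::with_seed(99, x <- rnorm(10000, 10, 1))
  field <- structure(tibble::tibble(d0_mm = x),
                     class = c("displacement_field", class(tibble::tibble())))
  dens <- displacement_density(field)
  expect_equal(dens$d0_mm[which.max(dens$density)], 10, tolerance = 0.2)
  integral <- vesica:::trapz(dens$d0_mm, dens$density)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_error(displacement_density(field[1:5, ]), "at least 20")
  flat <- structure(tibble::tibble(d0_mm = rep(5, 30)),
                    class = c("displacement_field", class(tibble::tibble())))
  expect_warning(pm <- displacement_density(flat), "point mass")
  expect_identical(nrow(pm), 1L)
})

test_that("field construction fails for bad origins and open meshes", {
  pre <- make_sphere_mesh(30, 2)
  post <- make_sphere_mesh(20, 2)
  out <- spherical_frame(c(100, 0, 0))
  expect_error(compute_displacement_field(pre, post, out), "inside")
  open <- post
  open$faces <- open$faces[-1, , drop = FALSE]
  expect_error(compute_displacement_field(pre, open, spherical_frame(c(0, 0, 0))),
               "not closed")
})

test_that("uniform-sphere sampling gives resolution-independent statistics", {
  pre <- make_sphere_mesh(30, 3)
  post <- make_sphere_mesh(20, 3)
  f <- compute_displacement_field(pre, post, spherical_frame(c(0, 0, 0)),
                                  sampling = "uniform_sphere", n_samples = 500)
  expect_identical(nrow(f), 500L)
  expect_lt(max(abs(f$d0_mm - 10)) / 10, 0.02)
})
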