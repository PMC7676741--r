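test_that("void window is detected on clean and noisy curves", {
  curve <- make_area_curve(10, 40, 4000, 400, n_samples = 128, pad = 5)
  w <- detect_void_window(curve)
  # the raised-cosine start is tangentially flat, so the 1%-of-change
  # threshold crossing lags the true onset by ~6% of the duration
  expect_lt(abs(w[["t0"]] - 10), 2.5)
  expect_lt(abs(w[["tend"]] - 40), 2.5)

  noisy <- make_area_curve(10, 40, 4000, 400, n_samples = 128, pad = 5,
                           noise_sd = 0.01 * 3600, seed = 11)
  wn <- detect_void_window(noisy)
  expect_lt(abs(wn[["t0"]] - w[["t0"]]), 1)
  expect_lte(abs(wn[["tend"]] - w[["tend"]]), 1)

  flat <- tibble::tibble(time_s = 1:20, area_mm2 = rep(1000, 20))
  expect_error(detect_void_window(flat), "no voiding")
})

test_that("alpha endpoints are exact on any valid area curve", {
  for (noise in c(0, 40)) {
    curve <- make_area_curve(10, 40, 4000, 400, n_samples = 64,
                             noise_sd = noise, seed = 3)
    ac <- alpha_from_area(curve, t0 = 10, tend = 40)
    expect_identical(ac$alpha[1], 0)
    expect_identical(ac$alpha[nrow(ac)], 1)
    expect_true(all(ac$alpha >= 0 & ac$alpha <= 1))
  }
})

test_that("area-ratio square root inverts the canonical time course", {
  curve <- make_area_curve(10, 40, 4000, 400, n_samples = 64)
  ac <- alpha_from_area(curve, t0 = 10, tend = 40)
  ref <- alpha_sqrt_cosine(ac$time_s, 10, 40, warn = FALSE)
  expect_lt(max(abs(ac$alpha - ref)), 1e-12)
})

test_that("alpha at the mid-level area is sqrt(1/2)", {
  curve <- make_area_curve(0, 30, 2000, 200, n_samples = 61)
  ac <- alpha_from_area(curve, t0 = 0, tend = 30)
  mid <- which.min(abs(curve$area_mm2 - 1100))
  expect_equal(ac$alpha[ac$time_s == curve$time_s[mid]], sqrt(0.5),
               tolerance = 1e-6)
})

test_that("alpha is non-decreasing for monotone-decreasing areas", {
  curve <- make_area_curve(0, 30, 2000, 200, n_samples = 64,
                           noise_sd = 10, seed = 5)
  ac <- alpha_from_area(curve)
  violations <- sum(diff(ac$alpha) < -1e-9)
  expect_lte(violations, 2L)   # smoothing leaves at most isolated wiggles
  clean <- alpha_from_area(make_area_curve(0, 30, 2000, 200, n_samples = 64))
  expect_true(all(diff(clean$alpha) >= -1e-12))
})

test_that("degenerate area curves are rejected", {
  curve <- tibble::tibble(time_s = 0:10, area_mm2 = rep(500, 11))
  expect_error(alpha_from_area(curve, t0 = 0, tend = 10), "undefined")
})

test_that("square-root-of-cosine form: endpoints, midpoint, clamping", {
  expect_identical(alpha_sqrt_cosine(10, 10, 40), 0)
  expect_identical(alpha_sqrt_cosine(40, 10, 40), 1)
  expect_equal(alpha_sqrt_cosine(25, 10, 40), sqrt(0.5), tolerance = 1e-15)
  expect_warning(out <- alpha_sqrt_cosine(c(5, 45), 10, 40), "clamped")
  expect_identical(out, c(0, 1))
})

test_that("sqrt-cosine fit recovers its own parameters", {
  ac <- canonical_alpha(10, 40, 64)
  fit <- fit_sqrt_cosine(ac)
  expect_equal(fit$t0, 10, tolerance = 1e-6)
  expect_equal(fit$tend, 40, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-10)
  expect_identical(nrow(tidy(fit)), 2L)
  expect_error(fit_sqrt_cosine(ac[1:2, ]), "at least 8")
})

test_that("sqrt-cosine fit is robust to alpha noise across seeds", {
  ac <- canonical_alpha(10, 40, 64)
  for (seed in 1:20) {
    noisy <- ac
    noisy$alpha <- withr::with_seed(seed, ac$alpha + rnorm(64, 0, 0.02))
    fit <- fit_sqrt_cosine(noisy)
    expect_lt(abs(fit$t0 - 10), 0.5)
    expect_lt(abs(fit$tend - 40), 0.5)
  }
})

test_that("geometry interpolation is the radial model", {
  sf <- scenario_field("uniform", r_pre = 30, shrink_fraction = 1 / 3,
                       mesh_subdivisions = 3)
  pre <- sf$pair$pre
  field <- sf$field
  expect_identical(interpolate_geometry(pre, field, alpha = 0), pre)
  full <- interpolate_geometry(pre, field, alpha = 1)
  expect_equal(sqrt(rowSums(full$vertices^2)),
               rep(20, nrow(full$vertices)), tolerance = 1e-9)
  half <- interpolate_geometry(pre, field, alpha = 0.5)
  expect_equal(sqrt(rowSums(half$vertices^2)),
               rep(25, nrow(half$vertices)), tolerance = 1e-9)
  expect_identical(nrow(half$faces), nrow(pre$faces))
})

test_that("volume and flow conserve the voided volume exactly on a uniform grid", {
  sf <- scenario_field("dome_weighted", r_pre = 30, shrink_fraction = 0.25,
                       mesh_subdivisions = 3)
  kin <- volume_and_flow(sf$pair$pre, sf$field,
                         alpha_curve = canonical_alpha(10, 40, 64))
  voided <- kin$volume_mm3[1] - kin$volume_mm3[nrow(kin)]
  intQ <- vesica:::trapz(kin$time_s, kin$flow_ml_s) * 1000
  expect_equal(intQ, voided, tolerance = 0.005)
  expect_true(all(kin$flow_ml_s >= -1e-12))
})

test_that("constant alpha produces zero flow", {
  sf <- scenario_field("uniform", r_pre = 30, shrink_fraction = 1 / 3,
                       mesh_subdivisions = 2)
  flatc <- tibble::tibble(time_s = seq(0, 10, length.out = 16),
                          alpha = rep(0.5, 16))
  kin <- volume_and_flow(sf$pair$pre, sf$field, alpha_curve = flatc)
  expect_lt(max(abs(kin$flow_ml_s)), 1e-12)
})

test_that("flow rate matches the closed-form shrinking sphere", {
  sf <- scenario_field("uniform", r_pre = 30, shrink_fraction = 1 / 3,
                       mesh_subdivisions = 3)
  n <- 200L
  tg <- seq(0, 30, length.out = n)
  al <- alpha_sqrt_cosine(tg, 0, 30, warn = FALSE)
  kin <- volume_and_flow(sf$pair$pre, sf$field,
                         alpha_curve = tibble::tibble(time_s = tg, alpha = al))
  # R(t) = 30 - 10 alpha(t); Q = -4 pi R^2 dR/dt (scaled by the constant
  # mesh-vs-sphere volume ratio, which cancels to within the tolerance);
  # with alpha = sin(pi tau / 2), d alpha/dt = (pi / 2T) cos(pi tau / 2)
  Rt <- 30 - 10 * al
  dal <- (pi / (2 * 30)) * cos(pi * tg / (2 * 30))
  Q_an <- 4 * pi * Rt^2 * 10 * dal / 1000
  interior <- 5:(n - 5)
  expect_lt(max(abs(kin$flow_ml_s[interior] - Q_an[interior]) /
                  max(Q_an)), 0.01)
})

test_that("area shrink rate is bell-shaped; flow vanishes at the end of voiding", {
  # the sigmoidal area curve empties slowest at the start and end of voiding:
  # -dA/dt is zero at both ends with a single interior maximum
  curve <- make_area_curve(0, 30, 3000, 300, n_samples = 101)
  rate <- -diff(curve$area_mm2) / diff(curve$time_s)
  peak <- which.max(rate)
  expect_lt(rate[1], 0.05 * rate[peak])
  expect_lt(rate[100], 0.05 * rate[peak])
  expect_true(all(diff(rate[1:peak]) >= -1e-9))
  expect_true(all(diff(rate[peak:100]) <= 1e-9))

  # the volume flow rate of the radial model under the same time course is
  # monotone decreasing (alpha rises fastest at onset) and vanishes at tend
  sf <- scenario_field("uniform", r_pre = 30, shrink_fraction = 1 / 3,
                       mesh_subdivisions = 2)
  kin <- volume_and_flow(sf$pair$pre, sf$field,
                         alpha_curve = canonical_alpha(0, 30, 101))
  q <- kin$flow_ml_s
  expect_lt(q[101], 0.02 * max(q))
  expect_true(all(diff(q) <= 1e-9))
})
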