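#' Run configuration
#'
#' Validated bundle of inputs for the pipeline entry points. Paths are
#' checked up front so configuration errors surface before any computation;
#' the configuration is serialized verbatim into the output directory for
#' provenance.
#'
#' @param pre,post STL paths (pre- and post-void surfaces), or
#'   `surface_mesh` objects.
#' @param area area-curve CSV path (`time_s`, `area_mm2`), a tibble, or
#'   `NULL` when `alpha_source = "canonical"`.
#' @param axes 3x3 orthonormal frame axes (columns x = left, y = anterior,
#'   z = superior). Identity for the synthetic fixtures.
#' @param sampling displacement sampling mode (see
#'   [compute_displacement_field()]).
#' @param alpha_source `"measured"` (derive alpha from the area curve) or
#'   `"canonical"` (square-root-of-cosine with `t0`/`tend`) — the latter is
#'   how a measured time course is reused for subjects without real-time
#'   imaging.
#' @param t0,tend voiding window (s) for `"canonical"` alpha; detected from
#'   the area curve otherwise.
#' @param n_time_samples uniform time grid size for kinematics.
#' @param urethra_d,urethra_l urethra diameter and length (mm).
#' @param grid_h,cfl flow-solver grid spacing (mm) and CFL number.
#' @param fluid_density,fluid_viscosity fluid properties (kg/m^3, Pa s).
#' @param plane cut plane for the flow domain.
#' @param out output directory.
#' @param seed integer seed (recorded; the pipeline itself is deterministic).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(pre, post, area = NULL, axes = diag(3),
                       sampling = "pre_vertices",
                       alpha_source = c("measured", "canonical"),
                       t0 = NULL, tend = NULL, n_time_samples = 64L,
                       urethra_d = 5, urethra_l = 20, grid_h = NULL,
                       cfl = 0.4, fluid_density = 1000,
                       fluid_viscosity = 7e-4,
                       plane = "sagittal", out = tempfile("vesica_run_"),
                       seed = 1L) {
  alpha_source <- match.arg(alpha_source)
  for (p in list(pre, post)) {
    if (!is_surface_mesh(p) && !file.exists(p)) {
      stop("mesh input not found: ", p, call. = FALSE)
    }
  }
  if (alpha_source == "measured") {
    if (is.null(area)) {
      stop("alpha_source = \"measured\" requires an area curve", call. = FALSE)
    }
    if (!is.data.frame(area) && !file.exists(area)) {
      stop("area curve file not found: ", area, call. = FALSE)
    }
  } else if (is.null(t0) || is.null(tend)) {
    stop("alpha_source = \"canonical\" requires t0 and tend", call. = FALSE)
  }
  structure(list(
    pre = pre, post = post, area = area, axes = axes, sampling = sampling,
    alpha_source = alpha_source, t0 = t0, tend = tend,
    n_time_samples = as.integer(n_time_samples),
    urethra_d = urethra_d, urethra_l = urethra_l, grid_h = grid_h, cfl = cfl,
    fluid_density = fluid_density, fluid_viscosity = fluid_viscosity,
    plane = plane, out = out, seed = as.integer(seed)
  ), class = "run_config")
}

config_json <- function(config) {
  ser <- config
  ser$pre <- if (is_surface_mesh(config$pre)) "<in-memory mesh>" else config$pre
  ser$post <- if (is_surface_mesh(config$post)) "<in-memory mesh>" else config$post
  ser$area <- if (is.data.frame(config$area)) "<in-memory curve>" else config$area
  ser$axes <- as.vector(config$axes)
  unclass(ser)
}

load_mesh_input <- function(x, label) {
  if (is_surface_mesh(x)) x else read_stl(x, provenance = label)
}

#' Run the displacement + kinematics pipeline
#'
#' Executes mesh validation, radial displacement-field estimation, regional
#' and asymmetry statistics, the displacement probability density, the
#' voiding time course and the volume/flow kinematics, writing tabular
#' outputs and a JSON summary to the configured directory.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `field`, `stats`, `alpha_curve`,
#'   `kinematics`, `summary` (also written to `summary.json`).
#' @export
run_displacement_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config_json(config), file.path(config$out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  pre <- load_mesh_input(config$pre, "pre-void")
  post <- load_mesh_input(config$post, "post-void")
  frame <- frame_from_post_void(post, axes = config$axes)

  field <- compute_displacement_field(pre, post, frame, sampling = config$sampling)
  stats <- regional_stats(field)
  dens <- displacement_density(field)

  if (config$alpha_source == "measured") {
    curve <- if (is.data.frame(config$area)) {
      tibble::as_tibble(config$area)
    } else {
      read_area_curve(config$area)
    }
    ac <- alpha_from_area(curve, t0 = config$t0, tend = config$tend)
    t0 <- attr(ac, "t0")
    tend <- attr(ac, "tend")
  } else {
    t0 <- config$t0
    tend <- config$tend
  }
  tgrid <- seq(t0, tend, length.out = config$n_time_samples)
  alpha_curve <- tibble::tibble(
    time_s = tgrid,
    alpha = if (config$alpha_source == "measured") {
      approx(ac$time_s, ac$alpha, xout = tgrid, rule = 2)$y
    } else {
      alpha_sqrt_cosine(tgrid, t0, tend, warn = FALSE)
    }
  )
  kin <- volume_and_flow(pre, field, frame, alpha_curve, keep_meshes = TRUE)

  utils::write.csv(as.data.frame(field), file.path(config$out, "displacement_field.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(stats), file.path(config$out, "regional_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dens), file.path(config$out, "displacement_density.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(alpha_curve), file.path(config$out, "alpha_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(kin[, c("time_s", "alpha", "volume_mm3", "flow_ml_s")]),
                   file.path(config$out, "kinematics.csv"), row.names = FALSE)

  gk <- glance(kin)
  summary <- list(
    n_samples = nrow(field),
    n_failed_rays = attr(field, "n_failed"),
    median_d0_mm = signif(median(field$d0_mm), 6),
    asymmetry_pct = signif(attr(stats, "asymmetry_pct"), 6),
    median_left_mm = signif(stats$median[stats$region == "left"], 6),
    median_right_mm = signif(stats$median[stats$region == "right"], 6),
    median_dome_mm = signif(stats$median[stats$region == "dome"], 6),
    median_base_mm = signif(stats$median[stats$region == "base"], 6),
    t0_s = t0, tend_s = tend,
    v_pre_ml = signif(gk$v_pre_ml, 6), v_post_ml = signif(gk$v_post_ml, 6),
    voided_ml = signif(gk$voided_ml, 6), q_max_ml_s = signif(gk$q_max_ml_s, 6),
    alpha_source = config$alpha_source, seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(field = field, stats = stats, density = dens,
                 alpha_curve = alpha_curve, kinematics = kin, summary = summary))
}

#' Run the voiding flow pipeline
#'
#' Builds the 2D flow domain from the displacement-pipeline kinematics (run
#' inline when not supplied), solves the moving-boundary flow, and writes the
#' metric time series and a JSON summary (time-averaged mean vorticity,
#' dimensionless vorticity, peak recirculation fraction, mass-conservation
#' check).
#'
#' @param config a [run_config()].
#' @param displacement optional result of [run_displacement_pipeline()].
#' @return Invisibly, a list with `domain`, `solution`, `metrics`, `summary`.
#' @export
run_flow_pipeline <- function(config, displacement = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(displacement)) displacement <- run_displacement_pipeline(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  domain <- build_domain(
    displacement$kinematics, plane = config$plane,
    urethra = c(D = config$urethra_d, L = config$urethra_l),
    fluid = c(density = config$fluid_density, viscosity = config$fluid_viscosity)
  )
  grid_h <- if (is.null(config$grid_h)) config$urethra_d / 8 else config$grid_h
  sol <- solve_voiding_flow(domain, grid_h = grid_h, cfl = config$cfl)
  metrics <- flow_metrics(sol)
  gf <- glance(sol)
  utils::write.csv(as.data.frame(metrics), file.path(config$out, "flow_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sol$diagnostics),
                   file.path(config$out, "flow_diagnostics.csv"), row.names = FALSE)
  summary <- list(
    mean_vorticity_per_s = signif(gf$mean_vorticity_per_s, 6),
    dimensionless_vorticity = signif(gf$dimensionless_vorticity, 6),
    peak_recirc_fraction = signif(gf$peak_recirc_fraction, 6),
    q_mean_mm2_s = signif(gf$q_mean_mm2_s, 6),
    max_div_rel = signif(gf$max_div_rel, 6),
    max_mass_error_rel = signif(gf$max_mass_error_rel, 6),
    mass_conservation_pass = gf$max_mass_error_rel < 0.02,
    n_steps = gf$n_steps
  )
  jsonlite::write_json(summary, file.path(config$out, "flow_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(domain = domain, solution = sol, metrics = metrics,
                 summary = summary))
}
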