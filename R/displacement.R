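#' Radial wall-displacement field between pre- and post-void surfaces
#'
#' Implements the separable radial-motion model: bladder-wall displacement is
#' assumed purely radial about the bladder-centric origin, so the tangential
#' components are identically zero and the total displacement along each
#' sampled direction is `d0 = r_pre - r_post`, the distance between the two
#' anatomies measured by ray casting.
#'
#' Sampling modes: `"pre_vertices"` (default) samples the directions of the
#' pre-void vertices, so the field can later drive vertex-wise geometry
#' interpolation; `"uniform_sphere"` samples `n_samples` near-uniform
#' (Fibonacci) directions for mesh-resolution-independent statistics.
#'
#' @param pre,post closed [surface_mesh()]es (mm).
#' @param frame a [spherical_frame()]; defaults to the post-void centroid
#'   frame with canonical axes. Its origin must lie inside both meshes.
#' @param sampling `"pre_vertices"` or `"uniform_sphere"`.
#' @param n_samples number of directions for `"uniform_sphere"` sampling.
#' @param max_fail_frac error if more than this fraction of rays fail
#'   (meshes likely not star-shaped about the origin).
#' @return A tibble of class `displacement_field` with one row per retained
#'   sample: `theta_rad`, `phi_rad`, `r_pre_mm`, `r_post_mm`, `d0_mm`,
#'   `dtheta_mm`, `dphi_mm` (identically 0 under the model),
#'   `multiplicity_pre`, `multiplicity_post`, and (after
#'   [partition_regions()], applied automatically) `region_ap`, `region_db`,
#'   `region_lr`. Attributes: `frame`, `sampling`, `n_failed`, `vertex_index`
#'   (pre-vertex row for each sample when sampling on pre vertices).
#' @export
compute_displacement_field <- function(pre, post, frame = frame_from_post_void(post),
                                       sampling = c("pre_vertices", "uniform_sphere"),
                                       n_samples = 2000L, max_fail_frac = 0.05) {
  sampling <- match.arg(sampling)
  stopifnot(is_surface_mesh(pre), is_surface_mesh(post))
  for (m in list(pre, post)) {
    rep <- validate_mesh(m)
    if (!rep$closed) stop("mesh '", m$provenance, "' is not closed", call. = FALSE)
  }
  if (!point_in_mesh(pre, frame$origin) || !point_in_mesh(post, frame$origin)) {
    stop("frame origin must lie strictly inside both meshes", call. = FALSE)
  }

  if (sampling == "pre_vertices") {
    rel <- sweep(pre$vertices, 2, frame$origin, `-`)
    r_pre_direct <- sqrt(rowSums(rel^2))
    dirs <- rel / r_pre_direct
    vertex_index <- seq_len(nrow(pre$vertices))
  } else {
    dirs <- fibonacci_directions(n_samples)
    vertex_index <- rep(NA_integer_, n_samples)
  }
  ang <- frame_angles(frame, dirs)

  cast_post <- mesh_caster(post)
  n <- nrow(dirs)
  r_post <- numeric(n)
  mult_post <- integer(n)
  for (i in seq_len(n)) {
    h <- cast_all_hits(cast_post, frame$origin, dirs[i, ])
    if (length(h) == 0L) {
      r_post[i] <- NA_real_
      mult_post[i] <- 0L
    } else {
      r_post[i] <- h[1]
      mult_post[i] <- length(h)
    }
  }
  if (sampling == "pre_vertices") {
    r_pre <- r_pre_direct
    mult_pre <- rep(1L, n)
  } else {
    cast_pre <- mesh_caster(pre)
    r_pre <- numeric(n)
    mult_pre <- integer(n)
    for (i in seq_len(n)) {
      h <- cast_all_hits(cast_pre, frame$origin, dirs[i, ])
      if (length(h) == 0L) {
        r_pre[i] <- NA_real_
        mult_pre[i] <- 0L
      } else {
        r_pre[i] <- h[1]
        mult_pre[i] <- length(h)
      }
    }
  }

  failed <- is.na(r_pre) | is.na(r_post)
  if (mean(failed) > max_fail_frac) {
    stop(sprintf(
      "%.1f%% of sample rays failed (> %.0f%%): meshes are likely not star-shaped about the chosen origin",
      100 * mean(failed), 100 * max_fail_frac), call. = FALSE)
  }
  keep <- !failed
  field <- tibble::tibble(
    theta_rad = ang$theta[keep], phi_rad = ang$phi[keep],
    r_pre_mm = r_pre[keep], r_post_mm = r_post[keep],
    d0_mm = r_pre[keep] - r_post[keep],
    dtheta_mm = 0, dphi_mm = 0,
    multiplicity_pre = mult_pre[keep], multiplicity_post = mult_post[keep]
  )
  field <- structure(field, class = c("displacement_field", class(tibble::tibble())),
                     frame = frame, sampling = sampling,
                     n_failed = sum(failed),
                     vertex_index = vertex_index[keep])
  partition_regions(field, frame)
}

# near-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(r * cos(ga * i), r * sin(ga * i), z)
}

#' Label samples by anatomical region
#'
#' Divides the bladder wall into anterior/posterior, dome/base and left/right
#' halves by coordinate sign in the bladder frame (three independent binary
#' labels per sample). Samples exactly on a boundary plane go to the positive
#' side, deterministically.
#'
#' @param field a `displacement_field` tibble.
#' @param frame the [spherical_frame()] (defaults to the field's own).
#' @return The field with columns `region_ap`, `region_db`, `region_lr`.
#' @export
partition_regions <- function(field, frame = attr(field, "frame")) {
  local <- cbind(sin(field$theta_rad) * cos(field$phi_rad),
                 sin(field$theta_rad) * sin(field$phi_rad),
                 cos(field$theta_rad))
  field$region_ap <- ifelse(local[, 2] >= 0, "anterior", "posterior")
  field$region_db <- ifelse(local[, 3] >= 0, "dome", "base")
  field$region_lr <- ifelse(local[, 1] >= 0, "left", "right")
  field
}

#' Regional five-number summaries and the left-right asymmetry ratio
#'
#' @param field a `displacement_field` with region labels.
#' @param min_samples error if any region has fewer samples than this.
#' @return A tibble of class `regional_stats` with one row per region
#'   (anterior, posterior, dome, base, left, right): `n`, `min`, `q1`,
#'   `median`, `q3`, `max` of `d0_mm`; attribute `asymmetry_pct` holds the
#'   left-right asymmetry ratio (also in [glance()]).
#' @export
regional_stats <- function(field, min_samples = 5L) {
  longer <- tidyr::pivot_longer(
    tibble::as_tibble(field)[, c("d0_mm", "region_ap", "region_db", "region_lr")],
    cols = c("region_ap", "region_db", "region_lr"),
    names_to = NULL, values_to = "region"
  )
  longer$region <- factor(longer$region, levels = c(
    "anterior", "posterior", "dome", "base", "left", "right"))
  stats <- dplyr::summarise(
    dplyr::group_by(longer, .data$region, .drop = FALSE),
    n = dplyr::n(),
    min = suppressWarnings(min(.data$d0_mm)),
    q1 = quantile(.data$d0_mm, 0.25, names = FALSE, type = 7),
    median = median(.data$d0_mm),
    q3 = quantile(.data$d0_mm, 0.75, names = FALSE, type = 7),
    max = suppressWarnings(max(.data$d0_mm)),
    .groups = "drop"
  )
  if (any(stats$n < min_samples)) {
    bad <- stats$region[stats$n < min_samples]
    stop("region(s) with fewer than ", min_samples, " samples: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  asym <- asymmetry_ratio(stats$median[stats$region == "left"],
                          stats$median[stats$region == "right"])
  structure(stats, class = c("regional_stats", class(stats)),
            asymmetry_pct = asym)
}

#' @export
glance.regional_stats <- function(x, ...) {
  tibble::tibble(
    asymmetry_pct = attr(x, "asymmetry_pct"),
    median_left_mm = x$median[x$region == "left"],
    median_right_mm = x$median[x$region == "right"],
    median_dome_mm = x$median[x$region == "dome"],
    median_base_mm = x$median[x$region == "base"]
  )
}

#' Left-right asymmetry ratio
#'
#' Absolute difference of the left and right median wall displacements,
#' normalized by the mean of the two medians, in percent. This normalization
#' admits values above 100% (severely lateralized motion).
#'
#' @param median_left,median_right regional median displacements (mm), >= 0,
#'   not both zero.
#' @return Asymmetry ratio in percent.
#' @export
asymmetry_ratio <- function(median_left, median_right) {
  stopifnot(median_left >= 0, median_right >= 0)
  if (median_left == 0 && median_right == 0) {
    stop("both medians are 0: asymmetry ratio undefined", call. = FALSE)
  }
  100 * abs(median_left - median_right) / ((median_left + median_right) / 2)
}

#' Probability density of wall displacement
#'
#' Gaussian-kernel density estimate of `d0` with Silverman's rule-of-thumb
#' bandwidth by default.
#'
#' @param field a `displacement_field` (>= 20 samples).
#' @param bandwidth kernel bandwidth (mm) or `"auto"` for Silverman's rule.
#' @return Tibble with columns `d0_mm`, `density` integrating to 1 within
#'   1e-3. If all samples are identical, warns and returns a single-row point
#'   mass (`density = Inf` convention avoided: returns `density = NA` with
#'   attribute `point_mass`).
#' @export
displacement_density <- function(field, bandwidth = "auto") {
  x <- field$d0_mm
  if (length(x) < 20L) stop("need at least 20 samples", call. = FALSE)
  if (diff(range(x)) < 1e-12 * max(1, abs(x[1]))) {
    warning("all displacement samples identical: degenerate density (point mass)")
    out <- tibble::tibble(d0_mm = x[1], density = NA_real_)
    attr(out, "point_mass") <- TRUE
    return(out)
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(x) else as.numeric(bandwidth)
  d <- density(x, bw = bw, n = 512, cut = 4)
  tibble::tibble(d0_mm = d$x, density = d$y)
}

#' @export
glance.displacement_field <- function(x, ...) {
  st <- regional_stats(x)
  tibble::tibble(
    n_samples = nrow(x),
    n_failed = attr(x, "n_failed"),
    sampling = attr(x, "sampling"),
    median_d0_mm = median(x$d0_mm),
    asymmetry_pct = attr(st, "asymmetry_pct"),
    max_tangential_mm = max(abs(c(x$dtheta_mm, x$dphi_mm)))
  )
}
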