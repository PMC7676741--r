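#' Read / write area-curve CSV
#'
#' Column convention: `time_s`, `area_mm2`.
#'
#' @param path CSV path.
#' @return Tibble with columns `time_s`, `area_mm2`.
#' @export
read_area_curve <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "area_mm2") %in% names(df))) {
    stop("area curve CSV must have columns time_s, area_mm2", call. = FALSE)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  tibble::as_tibble(df[, c("time_s", "area_mm2")])
}

# pick the smoothing window: 5-sample moving average when the curve carries
# detectable noise, none when it is already smooth (the square root in the
# alpha computation amplifies noise near t0, but smoothing a clean curve
# would bias it)
auto_window <- function(x, window = 5L) {
  r <- x - moving_average(x, window)
  s <- stats::sd(r)
  if (!is.finite(s) || s <= 1e-12 * max(abs(x), 1)) return(1L)
  # noise leaves a serially anti-correlated residual; the bias of averaging a
  # smooth curved segment leaves a strongly positively correlated one
  ac1 <- suppressWarnings(stats::cor(r[-1], r[-length(r)]))
  if (is.finite(ac1) && ac1 > 0.5) 1L else window
}

# first index i with cond[i .. i + k - 1] all TRUE (guards against isolated
# noise spikes crossing a threshold); falls back to single-sample crossings
first_sustained <- function(cond, k = 3L) {
  n <- length(cond)
  for (kk in c(k, 1L)) {
    if (n >= kk) {
      run <- cond
      if (kk > 1) {
        for (j in seq_len(kk - 1)) {
          run <- run & c(cond[-seq_len(j)], rep(FALSE, j))
        }
      }
      hit <- which(run)
      if (length(hit) > 0) return(hit[1])
    }
  }
  NA_integer_
}

# centred moving average; window must be odd
moving_average <- function(x, window = 5L) {
  if (length(x) < window) return(x)
  k <- rep(1 / window, window)
  sm <- stats::filter(x, k, sides = 2)
  half <- (window - 1L) %/% 2L
  # shrink the window near the ends instead of dropping samples
  n <- length(x)
  for (i in seq_len(half)) {
    sm[i] <- mean(x[1:(i + half)])
    sm[n - i + 1] <- mean(x[(n - i + 1 - half):n])
  }
  as.numeric(sm)
}

#' Detect the voiding window on an area curve
#'
#' Works on a 5-sample moving-average smoothed curve. `t0` is the last time
#' before the smoothed area first drops below `A_start - 1%` of the total
#' change; `tend` the first time it reaches `A_end + 1%` of the total change.
#' The plateau levels `A_start`/`A_end` are medians of the top/bottom sample
#' deciles, and threshold crossings must hold for three consecutive samples,
#' so isolated noise spikes do not trigger detection. Because a sigmoidal
#' emptying curve leaves its plateau tangentially, the detected window is
#' systematically a few percent of the voiding duration inside the true one.
#'
#' @param curve tibble with `time_s`, `area_mm2`.
#' @param smooth_window moving-average window (samples, odd), or `NULL` to
#'   smooth only when the curve carries detectable noise.
#' @return Named numeric `c(t0, tend)` (s).
#' @export
detect_void_window <- function(curve, smooth_window = NULL) {
  stopifnot(all(c("time_s", "area_mm2") %in% names(curve)))
  if (is.null(smooth_window)) smooth_window <- auto_window(curve$area_mm2)
  t <- curve$time_s
  a <- moving_average(curve$area_mm2, smooth_window)
  # plateau levels as medians of the top/bottom sample deciles (robust to
  # noise spikes, unlike the raw extremes)
  qs <- quantile(a, c(0.9, 0.1), names = FALSE)
  a_start <- median(a[a >= qs[1]])
  a_end <- median(a[a <= qs[2]])
  total <- a_start - a_end
  resid <- stats::sd(curve$area_mm2 - a)
  if (!is.finite(total) || total <= 0 || total <= 10 * max(resid, .Machine$double.eps)) {
    stop("no voiding event detected: total area change too small", call. = FALSE)
  }
  i_below <- first_sustained(a < a_start - 0.01 * total)
  if (is.na(i_below)) stop("no monotone drop found in area curve", call. = FALSE)
  i0 <- max(1L, i_below - 1L)
  reach_cond <- a <= a_end + 0.01 * total
  reach_cond[seq_len(i0)] <- FALSE
  i_end <- first_sustained(reach_cond)
  if (is.na(i_end)) stop("area curve never reaches its end plateau", call. = FALSE)
  c(t0 = t[i0], tend = t[i_end])
}

#' Time-dependence function from the area curve
#'
#' The dimensionless voiding time course derived from the real-time-imaging
#' bladder area: `alpha(t) = sqrt((A(t) - A(t0)) / (A(tend) - A(t0)))`,
#' evaluated on the smoothed curve. It varies from 0 at the start of voiding
#' to 1 at the end. Noise-driven ratio values below 0 are clipped to 0 before
#' the square root (the root amplifies noise near `t0`), and above 1 to 1.
#'
#' @param curve tibble with `time_s`, `area_mm2`.
#' @param t0,tend start/end of voiding (s); detected with
#'   [detect_void_window()] when omitted.
#' @param smooth_window moving-average window (samples), or `NULL` to smooth
#'   only when the curve carries detectable noise.
#' @return Tibble of class `alpha_curve` with columns `time_s`, `alpha`
#'   restricted to `[t0, tend]`; attributes `t0`, `tend`.
#' @export
alpha_from_area <- function(curve, t0 = NULL, tend = NULL, smooth_window = NULL) {
  if (is.null(smooth_window)) smooth_window <- auto_window(curve$area_mm2)
  if (is.null(t0) || is.null(tend)) {
    w <- detect_void_window(curve, smooth_window)
    if (is.null(t0)) t0 <- w[["t0"]]
    if (is.null(tend)) tend <- w[["tend"]]
  }
  a <- moving_average(curve$area_mm2, smooth_window)
  t <- curve$time_s
  A0 <- approx(t, a, xout = t0, rule = 2)$y
  Aend <- approx(t, a, xout = tend, rule = 2)$y
  if (Aend == A0) stop("A(tend) = A(t0): alpha undefined", call. = FALSE)
  keep <- t >= t0 & t <= tend
  tt <- unique(sort(c(t0, t[keep], tend)))
  aa <- approx(t, a, xout = tt, rule = 2)$y
  ratio <- (aa - A0) / (Aend - A0)
  alpha <- sqrt(pmin(1, pmax(0, ratio)))
  structure(tibble::tibble(time_s = tt, alpha = alpha),
            class = c("alpha_curve", class(tibble::tibble())),
            t0 = t0, tend = tend)
}

#' Square-root-of-cosine time-dependence function
#'
#' The parametric voiding time course `alpha(t) = sqrt((1 - cos(pi tau)) / 2)`
#' with `tau = (t - t0) / (tend - t0)`: 0 at the start of voiding, 1 at the
#' end, and inducing a sigmoidal (raised-cosine) area curve
#' `A = A0 + (Aend - A0) alpha^2`.
#'
#' @param t times (s); values outside `[t0, tend]` are clamped with a warning.
#' @param t0,tend start/end of voiding (s).
#' @param warn warn on clamping.
#' @return Numeric alpha values in `[0, 1]`.
#' @export
alpha_sqrt_cosine <- function(t, t0, tend, warn = TRUE) {
  stopifnot(tend > t0)
  tau <- (t - t0) / (tend - t0)
  if (warn && any(tau < 0 | tau > 1)) {
    warning("times outside [t0, tend] clamped")
  }
  tau <- pmin(1, pmax(0, tau))
  sqrt((1 - cos(pi * tau)) / 2)
}

#' Fit the square-root-of-cosine time course
#'
#' Least-squares fit of the two time parameters (`t0`, `tend`) of
#' [alpha_sqrt_cosine()] to a measured alpha curve.
#'
#' @param alpha_curve tibble with `time_s`, `alpha` (>= 8 samples).
#' @return Object of class `sqrt_cosine_fit`: list with `t0`, `tend`, `rmse`,
#'   `fitted` tibble, `convergence`. Supports [tidy()] and [glance()].
#' @export
fit_sqrt_cosine <- function(alpha_curve) {
  t <- alpha_curve$time_s
  a <- alpha_curve$alpha
  if (length(t) < 8L) stop("need at least 8 samples to fit", call. = FALSE)
  sse <- function(p) {
    if (p[2] - p[1] < .Machine$double.eps) return(1e10)
    sum((alpha_sqrt_cosine(t, p[1], p[2], warn = FALSE) - a)^2)
  }
  init <- c(min(t), max(t))
  fit <- optim(init, sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$convergence != 0) {
    stop("square-root-of-cosine fit did not converge (code ", fit$convergence,
         ", value ", signif(fit$value, 6), ")", call. = FALSE)
  }
  rmse <- sqrt(fit$value / length(t))
  structure(list(
    t0 = fit$par[1], tend = fit$par[2], rmse = rmse,
    fitted = tibble::tibble(
      time_s = t, alpha = a,
      alpha_fit = alpha_sqrt_cosine(t, fit$par[1], fit$par[2], warn = FALSE)
    ),
    convergence = fit$convergence
  ), class = "sqrt_cosine_fit")
}

#' @export
tidy.sqrt_cosine_fit <- function(x, ...) {
  tibble::tibble(term = c("t0", "tend"), estimate = c(x$t0, x$tend))
}

#' @export
glance.sqrt_cosine_fit <- function(x, ...) {
  tibble::tibble(t0 = x$t0, tend = x$tend, rmse = x$rmse,
                 duration_s = x$tend - x$t0, nobs = nrow(x$fitted))
}

#' @export
print.sqrt_cosine_fit <- function(x, ...) {
  cat(sprintf("<sqrt_cosine_fit: t0 = %.4f s, tend = %.4f s, rmse = %.3g>\n",
              x$t0, x$tend, x$rmse))
  invisible(x)
}

#' Interpolate voiding geometry at a given alpha
#'
#' Moves every pre-void vertex radially toward the frame origin by
#' `d0 * alpha` — the separable radial model's geometry at one instant of
#' voiding. Requires a field sampled on the pre-void vertices covering every
#' vertex. Topology is unchanged; `alpha = 0` returns the pre mesh unchanged.
#'
#' @param pre the pre-void [surface_mesh()].
#' @param field `displacement_field` sampled with `"pre_vertices"`.
#' @param frame the [spherical_frame()] used for the field.
#' @param alpha scalar in `[0, 1]`.
#' @return A [surface_mesh()].
#' @export
interpolate_geometry <- function(pre, field, frame = attr(field, "frame"), alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(attr(field, "sampling"), "pre_vertices")) {
    stop("field must be sampled on pre-void vertices", call. = FALSE)
  }
  vi <- attr(field, "vertex_index")
  if (length(vi) != nrow(pre$vertices) || anyNA(vi)) {
    stop("field does not cover every pre-void vertex (some rays failed)",
         call. = FALSE)
  }
  if (alpha == 0) return(pre)
  rel <- sweep(pre$vertices[vi, , drop = FALSE], 2, frame$origin, `-`)
  r <- sqrt(rowSums(rel^2))
  r_new <- r - field$d0_mm * alpha
  if (any(r_new <= 0)) {
    stop("interpolated radius <= 0 at ", sum(r_new <= 0), " vertex/vertices",
         call. = FALSE)
  }
  out <- pre
  out$vertices[vi, ] <- sweep(rel * (r_new / r), 2, frame$origin, `+`)
  out$provenance <- sprintf("interpolated(alpha=%.4f)", alpha)
  out
}

#' Volume curve and voiding flow rate from the imposed wall motion
#'
#' Interpolates the geometry at each alpha sample, computes the enclosed
#' volume `V(t)`, and the voiding flow rate `Q(t) = -dV/dt` by central
#' differences (one-sided at the ends), in mL/s. On a uniform time grid the
#' trapezoidal integral of `Q` telescopes to `V(t0) - V(tend)` exactly.
#'
#' @param pre the pre-void [surface_mesh()].
#' @param field `displacement_field` sampled on pre vertices.
#' @param frame the [spherical_frame()].
#' @param alpha_curve tibble with `time_s`, `alpha`, monotone non-decreasing.
#' @param keep_meshes retain the interpolated meshes as a list column.
#' @return Tibble of class `voiding_kinematics` with columns `time_s`,
#'   `alpha`, `volume_mm3`, `flow_ml_s` (and `mesh` if `keep_meshes`).
#' @export
volume_and_flow <- function(pre, field, frame = attr(field, "frame"),
                            alpha_curve, keep_meshes = FALSE) {
  t <- alpha_curve$time_s
  a <- alpha_curve$alpha
  if (any(diff(a) < -1e-12)) {
    warning("alpha curve is not monotone non-decreasing; Q may be negative")
  }
  meshes <- lapply(a, function(al) interpolate_geometry(pre, field, frame, al))
  V <- vapply(meshes, function(m) abs(signed_mesh_volume(m)), numeric(1))
  n <- length(t)
  dV <- numeric(n)
  dV[1] <- (V[2] - V[1]) / (t[2] - t[1])
  dV[n] <- (V[n] - V[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    dV[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  out <- tibble::tibble(time_s = t, alpha = a, volume_mm3 = V,
                        flow_ml_s = -dV / 1000)
  if (keep_meshes) out$mesh <- meshes
  structure(out, class = c("voiding_kinematics", class(tibble::tibble())),
            frame = frame)
}

#' @export
glance.voiding_kinematics <- function(x, ...) {
  voided <- (x$volume_mm3[1] - x$volume_mm3[nrow(x)]) / 1000
  tibble::tibble(
    v_pre_ml = x$volume_mm3[1] / 1000,
    v_post_ml = x$volume_mm3[nrow(x)] / 1000,
    voided_ml = voided,
    q_max_ml_s = max(x$flow_ml_s),
    q_mean_ml_s = voided / (x$time_s[nrow(x)] - x$time_s[1]),
    duration_s = x$time_s[nrow(x)] - x$time_s[1]
  )
}

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
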