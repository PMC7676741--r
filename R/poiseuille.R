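#' Pressure-driven channel flow (solver validation)
#'
#' Steady laminar flow through a straight rigid 2D channel, driven by a
#' kinematic pressure difference between the two open ends, computed with the
#' same staggered-grid discretization as [solve_voiding_flow()] (explicit
#' upwind advection, explicit diffusion, pressure projection, reflected-ghost
#' no-slip at the side walls). Marches to steady state; the analytic
#' solution is the Poiseuille parabola with maximum speed
#' `dp * D^2 / (8 nu L)`.
#'
#' @param D channel width (mm).
#' @param L channel length (mm).
#' @param nu kinematic viscosity (mm^2/s).
#' @param dp kinematic pressure drop (mm^2/s^2) from inlet (top) to outlet.
#' @param n_across cells across the channel width (>= 8).
#' @param tol steady-state tolerance: stop when the maximum velocity change
#'   per step falls below `tol * v_max_analytic`.
#' @param max_steps iteration cap.
#' @return Object of class `channel_flow`: `profile` tibble (`x_mm`,
#'   `v_mm_s` at mid-channel height), `v_max`, `v_max_analytic`,
#'   `max_div_rel`, `steps`, `converged`.
#' @export
solve_channel_flow <- function(D, L, nu = 0.7, dp = 50, n_across = 16L,
                               tol = 1e-7, max_steps = 50000L) {
  stopifnot(D > 0, L > 0, nu > 0, dp > 0)
  if (n_across < 8) stop("need at least 8 cells across the channel", call. = FALSE)
  nx <- as.integer(n_across)
  h <- D / nx
  ny <- max(4L, as.integer(round(L / h)))
  v_max_an <- dp * D^2 / (8 * nu * L)

  u <- matrix(0, nx + 1, ny)
  v <- matrix(0, nx, ny + 1)

  # static Poisson: all cells fluid, Dirichlet ghosts across top and bottom
  F <- matrix(TRUE, nx, ny)
  id <- matrix(seq_len(nx * ny), nx, ny)
  FE <- shift_mat(F, 1, 0, FALSE); FW <- shift_mat(F, -1, 0, FALSE)
  FN <- shift_mat(F, 0, 1, FALSE); FS <- shift_mat(F, 0, -1, FALSE)
  ndir <- matrix(0, nx, ny)
  ndir[, 1] <- ndir[, 1] + 1      # outlet (p = 0)
  ndir[, ny] <- ndir[, ny] + 1    # inlet (p = dp)
  nn <- FE + FW + FN + FS
  selE <- F & FE; idE <- shift_mat(id, 1, 0, 0L)
  selN <- F & FN; idN <- shift_mat(id, 0, 1, 0L)
  i_all <- c(id[selE], idE[selE], id[selN], idN[selN], as.vector(id))
  j_all <- c(idE[selE], id[selE], idN[selN], id[selN], as.vector(id))
  x_all <- c(rep(1, 2 * sum(selE) + 2 * sum(selN)), as.vector(-(nn + 2 * ndir)))
  A <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all / h^2,
                            dims = c(nx * ny, nx * ny))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(-A))
  rhs_bc <- matrix(0, nx, ny)
  rhs_bc[, ny] <- -2 * dp / h^2   # moved-to-RHS inlet Dirichlet term

  converged <- FALSE
  steps <- 0L
  p_mat <- matrix(0, nx, ny)
  for (k in seq_len(max_steps)) {
    steps <- k
    dt <- min(0.2 * h^2 / nu, 0.4 * h / max(abs(u), abs(v), 1e-9))
    # diffusion + advection for v (u stays ~0 but is evolved identically)
    ghost_v <- function(M, di, dj) {
      S <- shift_mat(M, di, dj, NA_real_)
      ifelse(is.na(S), -M, S)     # rigid side walls / ends: reflected no-slip
    }
    vE <- ghost_v(v, 1, 0); vW <- ghost_v(v, -1, 0)
    vN <- shift_mat(v, 0, 1, NA_real_); vS <- shift_mat(v, 0, -1, NA_real_)
    vN <- ifelse(is.na(vN), v, vN)  # zero-gradient along the axis at open ends
    vS <- ifelse(is.na(vS), v, vS)
    lap_v <- (vE + vW + vN + vS - 4 * v) / h^2
    dvdy <- ifelse(v > 0, (v - vS), (vN - v)) / h
    adv_v <- v * dvdy
    v_star <- v + dt * (-adv_v + nu * lap_v)

    uE <- shift_mat(u, 1, 0, 0); uW <- shift_mat(u, -1, 0, 0)
    uN <- shift_mat(u, 0, 1, NA_real_)
    uS <- shift_mat(u, 0, -1, NA_real_)
    uN <- ifelse(is.na(uN), -u, uN)
    uS <- ifelse(is.na(uS), -u, uS)
    lap_u <- (uE + uW + uN + uS - 4 * u) / h^2
    u_star <- u + dt * nu * lap_u
    u_star[1, ] <- 0
    u_star[nx + 1, ] <- 0

    div_star <- (u_star[2:(nx + 1), ] - u_star[1:nx, ] +
                   v_star[, 2:(ny + 1)] - v_star[, 1:ny]) / h
    rhs <- as.vector(div_star / dt + rhs_bc)
    p_vec <- as.numeric(Matrix::solve(ch, -rhs))
    p_mat <- matrix(p_vec, nx, ny)

    u_new <- u_star
    u_new[2:nx, ] <- u_star[2:nx, ] - dt * (p_mat[2:nx, ] - p_mat[1:(nx - 1), ]) / h
    v_new <- v_star
    v_new[, 2:ny] <- v_star[, 2:ny] - dt * (p_mat[, 2:ny] - p_mat[, 1:(ny - 1)]) / h
    v_new[, 1] <- v_star[, 1] - dt * (p_mat[, 1] - (-p_mat[, 1])) / h
    v_new[, ny + 1] <- v_star[, ny + 1] -
      dt * ((2 * dp - p_mat[, ny]) - p_mat[, ny]) / h

    dmax <- max(abs(v_new - v), abs(u_new - u))
    u <- u_new
    v <- v_new
    if (dmax < tol * v_max_an) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("channel flow not fully converged after ", steps, " steps")
  }
  div_final <- (u[2:(nx + 1), ] - u[1:nx, ] + v[, 2:(ny + 1)] - v[, 1:ny]) / h
  jmid <- max(1L, ny %/% 2L)
  profile <- tibble::tibble(
    x_mm = -D / 2 + (seq_len(nx) - 0.5) * h,
    v_mm_s = v[, jmid]
  )
  an_profile <- v_max_an * (1 - (2 * profile$x_mm / D)^2)
  structure(list(
    profile = profile,
    v_max = max(abs(v[, jmid])),
    v_max_analytic = v_max_an,
    profile_error_rel = max(abs(abs(profile$v_mm_s) - an_profile)) / v_max_an,
    max_div_rel = max(abs(div_final)) * h / max(abs(v), 1e-12),
    steps = steps, converged = converged,
    h = h, D = D, L = L, nu = nu, dp = dp
  ), class = "channel_flow")
}

#' @export
print.channel_flow <- function(x, ...) {
  cat(sprintf(
    "<channel_flow: v_max %.4g mm/s (analytic %.4g, err %.2f%%), %d steps%s>\n",
    x$v_max, x$v_max_analytic,
    100 * abs(x$v_max - x$v_max_analytic) / x$v_max_analytic,
    x$steps, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
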