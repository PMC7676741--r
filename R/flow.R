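#' Build the 2D moving-boundary flow domain for a voiding simulation
#'
#' Extracts the planar bladder contour from each interpolated geometry of a
#' voiding kinematics table (in radial form about the bladder-centric origin)
#' and attaches a straight rigid urethra channel of diameter `D` and length
#' `L` at the inferior contour point. The urethra outlet (far end of the
#' channel) is held at atmospheric (zero gauge) pressure during the
#' simulation; the bladder wall moves as prescribed by the radial model.
#'
#' @param kinematics a `voiding_kinematics` tibble built with
#'   `keep_meshes = TRUE` (see [volume_and_flow()]).
#' @param plane `"sagittal"` (default) or `"coronal"` cut through the frame
#'   origin; see [mesh_plane_contour()].
#' @param urethra named numeric `c(D = ..., L = ...)`: prostatic urethra
#'   diameter and channel length (mm).
#' @param fluid named numeric `c(density = ..., viscosity = ...)`: fluid
#'   density (kg/m^3) and dynamic viscosity (Pa s). Defaults are water-like
#'   urine at body temperature.
#' @param n_psi contour resolution (uniform polar angles).
#' @return Object of class `flow_domain`: contour radii over time plus
#'   channel and fluid parameters.
#' @export
build_domain <- function(kinematics, plane = c("sagittal", "coronal"),
                         urethra = c(D = 5, L = 20),
                         fluid = c(density = 1000, viscosity = 7e-4),
                         n_psi = 256L) {
  plane <- match.arg(plane)
  if (!"mesh" %in% names(kinematics)) {
    stop("kinematics must carry meshes (volume_and_flow(keep_meshes = TRUE))",
         call. = FALSE)
  }
  D <- unname(urethra[["D"]])
  L <- unname(urethra[["L"]])
  stopifnot(D > 0, L > 0)
  frame <- attr(kinematics, "frame")
  contours <- lapply(kinematics$mesh, mesh_plane_contour,
                     frame = frame, plane = plane, n_psi = n_psi)
  R <- do.call(rbind, lapply(contours, `[[`, "r"))
  psi <- contours[[1]]$psi
  if (D >= min(R)) {
    stop("urethra diameter D must be smaller than the bladder neck width ",
         sprintf("(min contour radius %.2f mm)", min(R)), call. = FALSE)
  }
  i_bot <- which.min(abs(psi + pi / 2))
  y_out <- -(R[1, i_bot] + L)
  nu <- fluid[["viscosity"]] / fluid[["density"]] * 1e6  # kinematic, mm^2/s
  structure(list(
    times = kinematics$time_s, psi = psi, R = R,
    area_mm2 = vapply(contours, `[[`, numeric(1), "area_mm2"),
    D = D, L = L, y_out = y_out, nu = nu, plane = plane,
    density = fluid[["density"]], viscosity = fluid[["viscosity"]]
  ), class = "flow_domain")
}

#' @export
print.flow_domain <- function(x, ...) {
  cat(sprintf(
    "<flow_domain: %d contours over [%.2f, %.2f] s, D = %.2f mm, L = %.2f mm, nu = %.3g mm^2/s>\n",
    length(x$times), min(x$times), max(x$times), x$D, x$L, x$nu))
  invisible(x)
}

# linear time interpolation of contour radii (rows of R)
domain_radii_at <- function(domain, t) {
  tt <- domain$times
  t <- min(max(t, tt[1]), tt[length(tt)])
  k <- findInterval(t, tt, rightmost.closed = TRUE)
  k <- min(max(k, 1L), length(tt) - 1L)
  w <- (t - tt[k]) / (tt[k + 1] - tt[k])
  domain$R[k, ] * (1 - w) + domain$R[k + 1, ] * w
}

# polygon area from uniform-angle radii
area_from_radii <- function(r) {
  dpsi <- 2 * pi / length(r)
  rn <- c(r[-1], r[1])
  sum(r * rn * sin(dpsi)) / 2
}

# value of M at (i+di, j+dj); `fill` outside
shift_mat <- function(M, di, dj, fill = NA_real_) {
  nr <- nrow(M)
  nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr)
  ci <- seq_len(nc)
  okr <- ri + di >= 1 & ri + di <= nr
  okc <- ci + dj >= 1 & ci + dj <= nc
  out[ri[okr], ci[okc]] <- M[ri[okr] + di, ci[okc] + dj]
  out
}

# angular interpolation setup: for query angles PSI (matrix), indices and
# weights into the uniform psi grid of length n_psi starting at -pi
psi_interp <- function(PSI, n_psi) {
  dpsi <- 2 * pi / n_psi
  f <- (PSI + pi) / dpsi
  j0 <- floor(f)
  w <- f - j0
  j1 <- (j0 %% n_psi) + 1L
  j2 <- (j1 %% n_psi) + 1L
  list(j1 = j1, j2 = j2, w = w)
}

interp_radii <- function(ip, r) {
  matrix(r[ip$j1] * (1 - ip$w) + r[ip$j2] * ip$w, nrow = nrow(ip$j1))
}

# sparse pressure Poisson matrix over fluid cells.
# F: fluid mask; dirich: mask of cells with a zero-pressure Dirichlet ghost
# across their bottom face (outlet). Returns list(A, id) with A in 1/h^2 units.
build_poisson <- function(F, dirich, h) {
  nx <- nrow(F)
  ny <- ncol(F)
  id <- matrix(0L, nx, ny)
  nf <- sum(F)
  id[F] <- seq_len(nf)
  FE <- shift_mat(F, 1, 0, FALSE)
  FW <- shift_mat(F, -1, 0, FALSE)
  FN <- shift_mat(F, 0, 1, FALSE)
  FS <- shift_mat(F, 0, -1, FALSE)
  nn <- (FE + FW + FN + FS)
  ii <- jj <- xx <- vector("list", 3)
  selE <- F & FE
  idE <- shift_mat(id, 1, 0, 0L)
  ii[[1]] <- id[selE]; jj[[1]] <- idE[selE]; xx[[1]] <- rep(1, sum(selE))
  selN <- F & FN
  idN <- shift_mat(id, 0, 1, 0L)
  ii[[2]] <- id[selN]; jj[[2]] <- idN[selN]; xx[[2]] <- rep(1, sum(selN))
  diagv <- -(nn[F] + 2 * (dirich[F]))
  ii[[3]] <- seq_len(nf); jj[[3]] <- seq_len(nf); xx[[3]] <- diagv
  i_all <- c(ii[[1]], jj[[1]], ii[[2]], jj[[2]], ii[[3]])
  j_all <- c(jj[[1]], ii[[1]], jj[[2]], ii[[2]], jj[[3]])
  x_all <- c(xx[[1]], xx[[1]], xx[[2]], xx[[2]], xx[[3]])
  A <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all / h^2,
                            dims = c(nf, nf))
  list(A = A, id = id)
}

#' Solve the prescribed-wall-motion voiding flow
#'
#' Incompressible Navier-Stokes on a uniform staggered (MAC) Cartesian grid
#' with a direct-forcing immersed boundary: wall faces take the prescribed
#' boundary velocity derived from the moving contour, the rigid urethra
#' channel is no-slip, and the outlet is zero gauge pressure with
#' zero-gradient velocity. Fractional-step (projection) scheme with explicit
#' upwind advection and explicit diffusion; the adaptive time step respects
#' both the advective CFL bound and the viscous stability bound. Wall-face
#' velocities are rescaled each step so the total wall influx matches the
#' contour-area shrink rate (discrete mass compatibility). Fully
#' deterministic.
#'
#' @param domain a [build_domain()] result.
#' @param grid_h requested grid spacing (mm); snapped so the channel is an
#'   even whole number of cells wide. At least 8 cells across `D` required.
#' @param cfl advective CFL number in (0, 0.5].
#' @param n_snapshots number of stored field snapshots (evenly spaced in
#'   time, including the initial state).
#' @param verbose print progress.
#' @return Object of class `flow_solution`: snapshot fields (cell-centred
#'   velocity, pressure, masks), per-step diagnostics (`diagnostics` tibble
#'   with outlet flux, wall influx, contour area, divergence), grid and
#'   domain parameters.
#' @export
solve_voiding_flow <- function(domain, grid_h, cfl = 0.4, n_snapshots = 21L,
                               verbose = FALSE) {
  stopifnot(inherits(domain, "flow_domain"), cfl > 0, cfl <= 0.5)
  D <- domain$D
  nD <- round(D / grid_h)
  if (nD %% 2 == 1) nD <- nD + 1
  if (nD < 8) {
    stop(sprintf(
      "channel under-resolved: %d cells across D; use grid_h <= %.4g mm",
      nD, D / 8), call. = FALSE)
  }
  h <- D / nD
  nu <- domain$nu
  maxR <- max(domain$R)
  Wx <- ceiling((maxR + 2 * h) / h) * h
  nx <- as.integer(round(2 * Wx / h))
  y_out <- domain$y_out
  ny <- as.integer(ceiling((Wx - y_out) / h))
  xc <- -Wx + (seq_len(nx) - 0.5) * h
  yc <- y_out + (seq_len(ny) - 0.5) * h
  xf <- -Wx + (seq_len(nx + 1) - 1) * h

  n_psi <- length(domain$psi)
  grid_geom <- function(X, Y) {
    RHO <- sqrt(X^2 + Y^2)
    PSI <- atan2(Y, X)
    c(list(RHO = RHO, PSI = PSI, X = X, Y = Y), psi_interp(PSI, n_psi))
  }
  Gc <- grid_geom(matrix(xc, nx, ny), matrix(yc, nx, ny, byrow = TRUE))
  Gu <- grid_geom(matrix(xf, nx + 1, ny), matrix(yc, nx + 1, ny, byrow = TRUE))
  Gv <- grid_geom(matrix(xc, nx, ny + 1),
                  matrix(c(y_out + (seq_len(ny + 1) - 1) * h), nx, ny + 1, byrow = TRUE))
  in_chan <- abs(Gc$X) < D / 2 & Gc$Y < 0

  dpsi <- 2 * pi / n_psi
  # level-set wall velocity components at a geometry set G for radii r_now
  # and angular radius rate rdot (per psi grid)
  wall_vel <- function(G, r_now_grid, rdot_grid) {
    r <- interp_radii(G, r_now_grid)
    rdot <- interp_radii(G, rdot_grid)
    rp_grid <- (c(r_now_grid[-1], r_now_grid[1]) -
                  c(r_now_grid[n_psi], r_now_grid[-n_psi])) / (2 * dpsi)
    rp <- interp_radii(G, rp_grid)
    rho <- pmax(G$RHO, 1e-9)
    cs <- cos(G$PSI)
    sn <- sin(G$PSI)
    gx <- cs + (rp / rho) * sn
    gy <- sn - (rp / rho) * cs
    g2 <- gx^2 + gy^2
    phi_t <- -rdot
    ux <- -phi_t * gx / g2
    uy <- -phi_t * gy / g2
    rigid <- G$Y < 0 & G$RHO >= r   # outside the bladder, below the equator
    ux[rigid] <- 0
    uy[rigid] <- 0
    list(ux = ux, uy = uy, r = r)
  }

  t0 <- domain$times[1]
  tend <- domain$times[length(domain$times)]
  snap_times <- seq(t0, tend, length.out = n_snapshots)
  eps_t <- (tend - t0) * 1e-4

  u <- matrix(0, nx + 1, ny)
  v <- matrix(0, nx, ny + 1)
  t_now <- t0
  snapshots <- list()
  diag_rows <- list()
  max_wall_speed <- max(abs(apply(domain$R, 2, diff) /
                              diff(domain$times))) + 1e-12

  take_snapshot <- function(tt, u, v, p_mat, F, in_poly, r_bottom) {
    u_c <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2
    v_c <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
    u_c[!F] <- NA_real_
    v_c[!F] <- NA_real_
    list(time_s = tt, u = u_c, v = v_c, p = p_mat, fluid = F,
         bladder = in_poly & F, outlet_point = c(0, -r_bottom))
  }

  r0 <- domain_radii_at(domain, t0)
  F0 <- Gc$RHO < interp_radii(Gc, r0) | in_chan
  in_poly0 <- Gc$RHO < interp_radii(Gc, r0)
  snapshots[[1]] <- take_snapshot(t0, u, v, matrix(NA_real_, nx, ny),
                                  F0, in_poly0, r0[which.min(abs(domain$psi + pi / 2))])
  next_snap <- 2L
  i_bot <- which.min(abs(domain$psi + pi / 2))
  dt_max <- (tend - t0) / 50
  step <- 0L

  while (t_now < tend - eps_t) {
    step <- step + 1L
    umax <- max(abs(u), abs(v), max_wall_speed, 1e-9)
    dt <- min(cfl * h / umax, 0.2 * h^2 / nu, dt_max, tend - t_now)
    if (next_snap <= n_snapshots && t_now + dt > snap_times[next_snap] - eps_t) {
      dt <- max(snap_times[next_snap] - t_now, dt_max * 1e-4)
    }
    t_new <- t_now + dt

    r_now <- domain_radii_at(domain, t_now)
    r_new <- domain_radii_at(domain, t_new)
    rdot <- (r_new - r_now) / dt
    A_now <- area_from_radii(r_now)
    A_new <- area_from_radii(r_new)
    target_influx <- (A_now - A_new) / dt   # > 0 while shrinking

    # masks at the new time
    rc <- interp_radii(Gc, r_new)
    in_poly <- Gc$RHO < rc
    F <- in_poly | in_chan
    # u-faces: cells (i-1, j) and (i, j)
    Fu_l <- rbind(matrix(FALSE, 1, ny), F)        # (nx+1) x ny
    Fu_r <- rbind(F, matrix(FALSE, 1, ny))
    active_u <- Fu_l & Fu_r
    wall_u <- xor(Fu_l, Fu_r)
    # v-faces: cells (i, j-1) and (i, j)
    Fv_b <- cbind(matrix(FALSE, nx, 1), F)        # nx x (ny+1)
    Fv_t <- cbind(F, matrix(FALSE, nx, 1))
    outlet_v <- matrix(FALSE, nx, ny + 1)
    outlet_v[, 1] <- F[, 1]
    active_v <- Fv_b & Fv_t
    wall_v <- xor(Fv_b, Fv_t) & !outlet_v

    wu <- wall_vel(Gu, r_new, rdot)
    wv <- wall_vel(Gv, r_new, rdot)

    # moving vs rigid wall faces: moving iff the face's fluid cell is inside
    # the bladder contour
    poly_u_l <- rbind(matrix(FALSE, 1, ny), in_poly)
    poly_u_r <- rbind(in_poly, matrix(FALSE, 1, ny))
    moving_u <- wall_u & ifelse(Fu_l, poly_u_l, poly_u_r)
    poly_v_b <- cbind(matrix(FALSE, nx, 1), in_poly)
    poly_v_t <- cbind(in_poly, matrix(FALSE, nx, 1))
    moving_v <- wall_v & ifelse(Fv_b, poly_v_b, poly_v_t)

    # raw influx through moving wall faces (+ if velocity points into fluid)
    sgn_u <- ifelse(Fu_r, 1, -1)   # fluid on +x side: +u enters
    sgn_v <- ifelse(Fv_t, 1, -1)
    raw <- sum(sgn_u[moving_u] * wu$ux[moving_u]) * h +
      sum(sgn_v[moving_v] * wv$uy[moving_v]) * h
    scale <- if (abs(raw) > 1e-12 * max(1, abs(target_influx))) {
      target_influx / raw
    } else 1
    WUg <- wu$ux * scale
    WVg <- wv$uy * scale

    # carry state onto new masks
    u[!(active_u | wall_u)] <- 0
    v[!(active_v | wall_v | outlet_v)] <- 0
    u[wall_u] <- ifelse(moving_u[wall_u], WUg[wall_u], 0)
    v[wall_v] <- ifelse(moving_v[wall_v], WVg[wall_v], 0)

    # ghost-aware neighbour fetch
    valid_u <- active_u | wall_u
    valid_v <- active_v | wall_v | outlet_v
    WUg[wall_u & !moving_u] <- 0
    WVg[wall_v & !moving_v] <- 0
    nb_u <- function(di, dj) {
      S <- shift_mat(u, di, dj, 0)
      V <- shift_mat(valid_u, di, dj, FALSE)
      Wn <- shift_mat(WUg, di, dj, 0)
      ifelse(V, S, 2 * Wn - u)
    }
    nb_v <- function(di, dj) {
      S <- shift_mat(v, di, dj, 0)
      V <- shift_mat(valid_v, di, dj, FALSE)
      Wn <- shift_mat(WVg, di, dj, 0)
      ifelse(V, S, 2 * Wn - v)
    }

    uE <- nb_u(1, 0); uW <- nb_u(-1, 0); uN <- nb_u(0, 1); uS <- nb_u(0, -1)
    lap_u <- (uE + uW + uN + uS - 4 * u) / h^2
    vfull <- ifelse(valid_v, v, WVg)
    vbar <- matrix(0, nx + 1, ny)
    vbar[2:nx, ] <- (vfull[1:(nx - 1), 1:ny] + vfull[1:(nx - 1), 2:(ny + 1)] +
                       vfull[2:nx, 1:ny] + vfull[2:nx, 2:(ny + 1)]) / 4
    dudx <- ifelse(u > 0, (u - uW), (uE - u)) / h
    dudy <- ifelse(vbar > 0, (u - uS), (uN - u)) / h
    adv_u <- u * dudx + vbar * dudy

    vE <- nb_v(1, 0); vW <- nb_v(-1, 0); vN <- nb_v(0, 1); vS <- nb_v(0, -1)
    lap_v <- (vE + vW + vN + vS - 4 * v) / h^2
    ufull <- ifelse(valid_u, u, WUg)
    ubar <- matrix(0, nx, ny + 1)
    ubar[, 2:ny] <- (ufull[1:nx, 1:(ny - 1)] + ufull[1:nx, 2:ny] +
                       ufull[2:(nx + 1), 1:(ny - 1)] + ufull[2:(nx + 1), 2:ny]) / 4
    dvdx <- ifelse(ubar > 0, (v - vW), (vE - v)) / h
    dvdy <- ifelse(v > 0, (v - vS), (vN - v)) / h
    adv_v <- ubar * dvdx + v * dvdy

    u_star <- u
    u_star[active_u] <- u[active_u] + dt * (-adv_u[active_u] + nu * lap_u[active_u])
    v_star <- v
    v_star[active_v] <- v[active_v] + dt * (-adv_v[active_v] + nu * lap_v[active_v])
    v_star[, 1][outlet_v[, 1]] <- v_star[, 2][outlet_v[, 1]]  # zero-gradient

    # pressure projection
    dirich <- matrix(FALSE, nx, ny)
    dirich[, 1] <- F[, 1]
    bp <- build_poisson(F, dirich, h)
    div_star <- (u_star[2:(nx + 1), ] - u_star[1:nx, ] +
                   v_star[, 2:(ny + 1)] - v_star[, 1:ny]) / h
    rhs <- div_star[F] / dt
    p_vec <- as.numeric(Matrix::solve(bp$A, rhs))
    resid <- max(abs(as.numeric(bp$A %*% p_vec) - rhs))
    if (!is.finite(resid) || resid > 1e-6 * max(1, max(abs(rhs)))) {
      stop("pressure solve failed to converge (residual ", signif(resid, 3), ")",
           call. = FALSE)
    }
    p_mat <- matrix(NA_real_, nx, ny)
    p_mat[F] <- p_vec
    p0 <- p_mat
    p0[!F] <- 0

    gpx <- (p0[2:nx, ] - p0[1:(nx - 1), ]) / h
    u[2:nx, ][active_u[2:nx, ]] <-
      u_star[2:nx, ][active_u[2:nx, ]] - dt * gpx[active_u[2:nx, ]]
    gpy <- (p0[, 2:ny] - p0[, 1:(ny - 1)]) / h
    v[, 2:ny][active_v[, 2:ny]] <-
      v_star[, 2:ny][active_v[, 2:ny]] - dt * gpy[active_v[, 2:ny]]
    ol <- outlet_v[, 1]
    v[, 1][ol] <- v_star[, 1][ol] - dt * 2 * p_mat[, 1][ol] / h

    div_new <- (u[2:(nx + 1), ] - u[1:nx, ] + v[, 2:(ny + 1)] - v[, 1:ny]) / h
    uchar <- max(abs(u), abs(v), 1e-12)
    outlet_flux <- -sum(v[, 1][ol]) * h
    diag_rows[[step]] <- tibble::tibble(
      time_s = t_new, dt_s = dt,
      max_div_rel = max(abs(div_new[F])) * h / uchar,
      outlet_flux_mm2_s = outlet_flux,
      wall_influx_mm2_s = target_influx,
      area_mm2 = A_new,
      dAdt_mm2_s = (A_new - A_now) / dt
    )
    t_now <- t_new
    if (next_snap <= n_snapshots && t_now >= snap_times[next_snap] - eps_t) {
      snapshots[[next_snap]] <- take_snapshot(
        t_now, u, v, p_mat, F, in_poly, interp_radii_scalar(r_new, domain$psi, -pi / 2))
      next_snap <- next_snap + 1L
    }
    if (verbose && step %% 50 == 0) {
      message(sprintf("t = %.3f / %.3f s (step %d, dt = %.4g)", t_now, tend, step, dt))
    }
  }

  structure(list(
    h = h, xc = xc, yc = yc,
    times = vapply(snapshots, `[[`, numeric(1), "time_s"),
    snapshots = snapshots,
    diagnostics = dplyr::bind_rows(diag_rows),
    D = D, L = domain$L, nu = nu, t0 = t0, tend = tend
  ), class = "flow_solution")
}

interp_radii_scalar <- function(r, psi, at) {
  n <- length(psi)
  dpsi <- 2 * pi / n
  f <- (at + pi) / dpsi
  j0 <- floor(f)
  w <- f - j0
  j1 <- (j0 %% n) + 1L
  j2 <- (j1 %% n) + 1L
  r[j1] * (1 - w) + r[j2] * w
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution: %d snapshots over [%.2f, %.2f] s, grid %.3g mm, %d steps>\n",
    length(x$snapshots), x$t0, x$tend, x$h, nrow(x$diagnostics)))
  invisible(x)
}

#' Vorticity of a 2D velocity field
#'
#' `omega = dv/dx - du/dy` by central differences on cell-centred fields;
#' defined on interior fluid cells (all four neighbours fluid), `NA`
#' elsewhere.
#'
#' @param u,v cell-centred velocity matrices (x index first).
#' @param h grid spacing (mm).
#' @param mask logical fluid mask (defaults to finite velocities).
#' @return Matrix of vorticity (1/s).
#' @export
vorticity_from_velocity <- function(u, v, h, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(u) & is.finite(v)
  u0 <- ifelse(mask, u, NA_real_)
  v0 <- ifelse(mask, v, NA_real_)
  om <- (shift_mat(v0, 1, 0) - shift_mat(v0, -1, 0)) / (2 * h) -
    (shift_mat(u0, 0, 1) - shift_mat(u0, 0, -1)) / (2 * h)
  om[!mask] <- NA_real_
  om
}

#' @param solution a `flow_solution`.
#' @param step snapshot index.
#' @rdname vorticity_from_velocity
#' @export
vorticity_field <- function(solution, step) {
  stopifnot(step >= 1, step <= length(solution$snapshots))
  s <- solution$snapshots[[step]]
  vorticity_from_velocity(s$u, s$v, solution$h, mask = s$fluid)
}

#' Mean bladder vorticity
#'
#' Area-weighted mean of `|omega|` over fluid cells inside the bladder
#' contour (the urethra channel excluded), per snapshot, plus the
#' time-average weighted by snapshot spacing.
#'
#' @param solution a `flow_solution`.
#' @return Tibble (`time_s`, `mean_abs_vorticity_per_s`) with attribute
#'   `time_average` (1/s).
#' @export
mean_vorticity <- function(solution) {
  per <- vapply(seq_along(solution$snapshots), function(k) {
    s <- solution$snapshots[[k]]
    om <- vorticity_from_velocity(s$u, s$v, solution$h, mask = s$fluid)
    vals <- abs(om[s$bladder])
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) stop("empty bladder mask at snapshot ", k, call. = FALSE)
    mean(vals)
  }, numeric(1))
  out <- tibble::tibble(time_s = solution$times, mean_abs_vorticity_per_s = per)
  ta <- trapz(solution$times, per) / diff(range(solution$times))
  attr(out, "time_average") <- ta
  out
}

#' Dimensionless vorticity
#'
#' Normalizes the mean vorticity by the mean urethral flow speed and the
#' prostatic urethra diameter, removing flow-rate differences between
#' subjects. Default mode treats the 2D outlet flux as flux per unit depth:
#' `Ubar = Q / D`, giving `omega * D / Ubar = omega * D^2 / Q`. The
#' `"pseudo3d"` mode instead uses a circular-duct mean speed
#' `Ubar = Q / (pi D^2 / 4)`.
#'
#' @param mean_vort mean |vorticity| (1/s).
#' @param Q_mean mean urethra flow rate (mm^2/s in 2D mode; mm^3/s pseudo-3D).
#' @param D urethra diameter (mm).
#' @param mode `"per_width"` (2D, default) or `"pseudo3d"`.
#' @return Dimensionless vorticity (scalar).
#' @export
dimensionless_vorticity <- function(mean_vort, Q_mean, D,
                                    mode = c("per_width", "pseudo3d")) {
  mode <- match.arg(mode)
  stopifnot(D > 0)
  if (Q_mean <= 0) stop("Q_mean must be > 0: normalization undefined", call. = FALSE)
  ubar <- switch(mode, per_width = Q_mean / D, pseudo3d = Q_mean / (pi * D^2 / 4))
  mean_vort * D / ubar
}

#' Recirculation fraction
#'
#' Fraction of bladder fluid cells whose velocity makes an angle greater than
#' 90 degrees with the local sink direction (unit vector from the cell toward
#' the outlet point), among cells moving faster than 1% of the snapshot's
#' maximum speed. Quantifies the reversed/closed streamline regions seen in
#' impaired voiding.
#'
#' @param solution a `flow_solution`.
#' @param step snapshot index.
#' @param outlet_point length-2 (a, b) point; defaults to the bladder neck at
#'   that snapshot.
#' @param speed_floor_frac speed threshold as a fraction of the maximum.
#' @return Fraction in `[0, 1]`.
#' @export
recirculation_fraction <- function(solution, step, outlet_point = NULL,
                                   speed_floor_frac = 0.01) {
  s <- solution$snapshots[[step]]
  if (is.null(outlet_point)) outlet_point <- s$outlet_point
  bl <- s$bladder
  uu <- s$u[bl]
  vv <- s$v[bl]
  X <- matrix(solution$xc, length(solution$xc), length(solution$yc))[bl]
  Y <- matrix(solution$yc, length(solution$xc), length(solution$yc), byrow = TRUE)[bl]
  sp <- sqrt(uu^2 + vv^2)
  spmax <- max(sp, na.rm = TRUE)
  if (!is.finite(spmax) || spmax == 0) {
    warning("all-quiescent snapshot: recirculation fraction 0")
    return(0)
  }
  moving <- is.finite(sp) & sp > speed_floor_frac * spmax
  if (!any(moving)) return(0)
  dx <- outlet_point[1] - X[moving]
  dy <- outlet_point[2] - Y[moving]
  dn <- sqrt(dx^2 + dy^2)
  dotp <- (uu[moving] * dx + vv[moving] * dy) / pmax(dn, 1e-12)
  mean(dotp < 0)
}

#' Flow metric time series
#'
#' @param solution a `flow_solution`.
#' @return Tibble (`time_s`, `mean_abs_vorticity_per_s`, `recirc_fraction`).
#' @export
flow_metrics <- function(solution) {
  mv <- mean_vorticity(solution)
  rf <- vapply(seq_along(solution$snapshots), function(k) {
    suppressWarnings(recirculation_fraction(solution, k))
  }, numeric(1))
  out <- tibble::tibble(time_s = mv$time_s,
                        mean_abs_vorticity_per_s = mv$mean_abs_vorticity_per_s,
                        recirc_fraction = rf)
  attr(out, "time_average_vorticity") <- attr(mv, "time_average")
  out
}

#' @export
glance.flow_solution <- function(x, ...) {
  met <- flow_metrics(x)
  d <- x$diagnostics
  w <- d$dt_s / sum(d$dt_s)
  q_mean <- sum(d$outlet_flux_mm2_s * w)
  mv <- attr(met, "time_average_vorticity")
  tibble::tibble(
    mean_vorticity_per_s = mv,
    dimensionless_vorticity = dimensionless_vorticity(mv, max(q_mean, 1e-12), x$D),
    peak_recirc_fraction = max(met$recirc_fraction),
    q_mean_mm2_s = q_mean,
    max_div_rel = max(d$max_div_rel),
    max_mass_error_rel = max(abs(d$outlet_flux_mm2_s - d$wall_influx_mm2_s) /
                               pmax(abs(d$wall_influx_mm2_s), 1e-9)),
    n_steps = nrow(d)
  )
}
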