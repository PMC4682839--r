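#' Rectangular microcapillary geometry and flow conditions
#'
#' Channel dimensions in mm, volumetric flow in ml/min, viscosity in
#' centipoise (converted to SI internally). The default values are the
#' microcapillary conditions used throughout: 2 x 0.2 mm cross-section,
#' 1.44 ml/min, 2.8 cP, giving a nominal wall shear rate of 1800 1/s.
#'
#' @param width_mm,height_mm,length_mm channel width (y), height (z), length
#'   (x); requires `height_mm <= width_mm`.
#' @param flow_ml_min volumetric flow rate.
#' @param viscosity_cP dynamic viscosity.
#' @param density_kg_m3 optional fluid density (needed for Reynolds number).
#' @return a `channel_geometry` object.
#' @export
channel_geometry <- function(width_mm = 2, height_mm = 0.2, length_mm = 100,
                             flow_ml_min = 1.44, viscosity_cP = 2.8,
                             density_kg_m3 = NULL) {
  stopifnot(width_mm > 0, height_mm > 0, length_mm > 0, flow_ml_min >= 0,
            viscosity_cP > 0)
  if (height_mm > width_mm) stopf("height must not exceed width (h <= w)")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 length_mm = length_mm, flow_ml_min = flow_ml_min,
                 viscosity_cP = viscosity_cP, density_kg_m3 = density_kg_m3,
                 # SI
                 w_m = width_mm * 1e-3, h_m = height_mm * 1e-3,
                 Q_m3_s = flow_ml_min * 1e-6 / 60,
                 mu_Pa_s = viscosity_cP * 1e-3),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %g x %g x %g mm, Q = %g ml/min, mu = %g cP\n",
              x$width_mm, x$height_mm, x$length_mm, x$flow_ml_min,
              x$viscosity_cP))
  cat(sprintf("  gamma_w = %.4g 1/s, D_h = %.4g mm, AR = %.4g\n",
              nominal_wall_shear(x), hydraulic_diameter(x), aspect_ratio(x)))
  invisible(x)
}

#' Nominal wall shear rate 6Q/(w h^2)
#'
#' Parallel-plate approximation of the wall shear rate for fully developed
#' flow in a wide rectangular duct.
#'
#' @param geom a [channel_geometry()].
#' @return wall shear rate (1/s).
#' @export
nominal_wall_shear <- function(geom) {
  Q_mm3_s <- geom$flow_ml_min * 1000 / 60
  6 * Q_mm3_s / (geom$width_mm * geom$height_mm^2)
}

#' Hydraulic diameter 2wh/(w+h)
#' @param geom a [channel_geometry()].
#' @return hydraulic diameter (mm).
#' @export
hydraulic_diameter <- function(geom)
  2 * geom$width_mm * geom$height_mm / (geom$width_mm + geom$height_mm)

#' Cross-section aspect ratio h/w
#' @param geom a [channel_geometry()].
#' @return dimensionless aspect ratio (0.1 for the 2 x 0.2 mm section).
#' @export
aspect_ratio <- function(geom) geom$height_mm / geom$width_mm

#' Reynolds number based on the hydraulic diameter
#'
#' Re = rho U_mean D_h / mu with U_mean = Q/(wh).
#'
#' @param geom a [channel_geometry()].
#' @param density_kg_m3 fluid density; defaults to the geometry's density.
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(geom, density_kg_m3 = geom$density_kg_m3) {
  if (is.null(density_kg_m3))
    stopf("Reynolds number requires a fluid density (kg/m^3)")
  U <- geom$Q_m3_s / (geom$w_m * geom$h_m)
  density_kg_m3 * U * (hydraulic_diameter(geom) * 1e-3) / geom$mu_Pa_s
}

# stable cosh(a)/cosh(b) and sinh(a)/cosh(b) for 0 <= |a| <= b
cosh_ratio <- function(a, b) {
  aa <- abs(a)
  exp(aa - b) * (1 + exp(-2 * aa)) / (1 + exp(-2 * b))
}
sinh_ratio <- function(a, b) {
  aa <- abs(a)
  sign(a) * exp(aa - b) * (1 - exp(-2 * aa)) / (1 + exp(-2 * b))
}

# odd-n Fourier coefficients normalising the duct profile to Q; returns
# list(n, C) with u = C * sum n^-3 [1 - cosh(n pi y/h)/cosh(n pi w/(2h))]
# sin(n pi z/h)
duct_series <- function(geom, n_max = 9999) {
  n <- seq(1, n_max, by = 2)
  w <- geom$w_m; h <- geom$h_m
  Qn <- n^-3 * (2 * h / (n * pi)) * (w - (2 * h / (n * pi)) * tanh(n * pi * w / (2 * h)))
  keep <- seq_len(max(which(cumsum(Qn) / sum(Qn) < 1 - 1e-12), 2))
  list(n = n[keep], C = geom$Q_m3_s / sum(Qn))
}

#' Analytic rectangular-duct velocity profile
#'
#' Exact Fourier-series axial velocity of fully developed laminar flow in a
#' rectangular duct, normalised so the cross-sectional integral equals the
#' volumetric flow rate. Coordinates: y across the width, centred
#' (|y| <= w/2); z the height above the floor (0 <= z <= h); both in um.
#'
#' @param geom a [channel_geometry()].
#' @param y_um,z_um coordinates (um), recycled to a common length.
#' @return axial velocity (m/s).
#' @export
analytic_duct_velocity <- function(geom, y_um, z_um) {
  pts <- cbind(y_um * 1e-6, z_um * 1e-6)
  w <- geom$w_m; h <- geom$h_m
  if (any(abs(pts[, 1]) > w / 2 + 1e-15) || any(pts[, 2] < -1e-15) ||
      any(pts[, 2] > h + 1e-15))
    stopf("point outside the duct cross-section")
  ser <- duct_series(geom)
  u <- numeric(nrow(pts))
  for (n in ser$n) {
    arg <- n * pi / h
    u <- u + n^-3 * (1 - cosh_ratio(arg * pts[, 1], arg * w / 2)) *
      sin(arg * pts[, 2])
  }
  ser$C * u
}

#' Analytic duct shear-rate magnitude
#'
#' sqrt((du/dy)^2 + (du/dz)^2) of the analytic profile: for unidirectional
#' flow this equals the local shear rate sqrt(2 D:D).
#'
#' @inheritParams analytic_duct_velocity
#' @param n_max series truncation for the (more slowly converging)
#'   derivative series.
#' @return shear rate (1/s).
#' @export
analytic_duct_shear <- function(geom, y_um, z_um, n_max = 20001) {
  pts <- cbind(y_um * 1e-6, z_um * 1e-6)
  w <- geom$w_m; h <- geom$h_m
  ser <- duct_series(geom)
  C <- ser$C
  duz <- numeric(nrow(pts)); duy <- numeric(nrow(pts))
  n <- seq(1, n_max, by = 2)
  for (nn in n) {
    arg <- nn * pi / h
    fac <- nn^-3 * arg
    duz <- duz + fac * (1 - cosh_ratio(arg * pts[, 1], arg * w / 2)) *
      cos(arg * pts[, 2])
    duy <- duy - fac * sinh_ratio(arg * pts[, 1], arg * w / 2) *
      sin(arg * pts[, 2])
  }
  C * sqrt(duy^2 + duz^2)
}

# graded face coordinates: density-based stretching concentrating cells in
# [focus_lo, focus_hi]; returns n+1 strictly increasing faces
grade_axis <- function(lo, hi, n, focus = NULL, strength = 3, sigma = NULL) {
  if (is.null(focus)) return(seq(lo, hi, length.out = n + 1))
  if (is.null(sigma)) sigma <- 0.2 * (focus[2] - focus[1])
  xs <- seq(lo, hi, length.out = 4001)
  dens <- 1 + strength * (stats::pnorm((xs - focus[1]) / sigma) -
                          stats::pnorm((xs - focus[2]) / sigma))
  cum <- cumsum(dens) - dens[1]
  cum <- cum / cum[length(cum)]
  faces <- stats::approx(cum, xs, xout = seq(0, 1, length.out = n + 1),
                         ties = "ordered")$y
  faces[1] <- lo; faces[n + 1] <- hi
  # bound the cell-to-cell expansion ratio (solver stability); the symmetric
  # Jacobi limiter preserves grid symmetry and the ratio is scale-invariant,
  # so renormalising to the domain length keeps it bounded
  d <- diff(faces)
  r_max <- 1.4
  for (it in seq_len(200)) {
    d2 <- pmin(d, r_max * c(d[1], head(d, -1)), r_max * c(tail(d, -1), d[n]))
    d2 <- d2 * (hi - lo) / sum(d2)
    if (max(abs(d2 - d)) < 1e-9 * (hi - lo)) { d <- d2; break }
    d <- d2
  }
  c(lo, lo + cumsum(d[-n]), hi)
}

#' Structured channel grid with local refinement
#'
#' Rectilinear face coordinates for the solver domain: x along the flow
#' (centred on 0), y across the width (centred), z from the floor. When an
#' obstacle (or bounding box) is given, cells are concentrated around it.
#'
#' @param geom a [channel_geometry()].
#' @param length_um domain length along the flow (a desk-scale section of the
#'   full channel; the inlet carries the fully developed analytic profile, so
#'   no entrance length is needed).
#' @param nx,ny,nz cell counts.
#' @param focus a [tri_surface], or list with elements x, y, z (ranges, um),
#'   or `NULL` for uniform spacing.
#' @param pad_um padding added around the focus region.
#' @param strength refinement strength per axis (cell-density ratio - 1,
#'   recycled to length 3); the y axis needs the strongest grading because
#'   the channel is 2 mm wide while a thrombus is ~10 um wide.
#' @return list with face coordinates `xf`, `yf`, `zf` (um).
#' @export
channel_grid <- function(geom, length_um = 600, nx = 48, ny = 36, nz = 24,
                         focus = NULL, pad_um = 25, strength = c(6, 30, 8)) {
  strength <- rep_len(strength, 3)
  w_um <- geom$width_mm * 1000; h_um <- geom$height_mm * 1000
  fx <- fy <- fz <- NULL
  if (!is.null(focus)) {
    if (inherits(focus, "tri_surface"))
      focus <- list(x = range(focus$vertices[, 1]),
                    y = range(focus$vertices[, 2]),
                    z = range(focus$vertices[, 3]))
    fx <- focus$x + c(-pad_um, pad_um)
    fy <- focus$y + c(-pad_um, pad_um)
    fz <- c(0, focus$z[2] + pad_um)
  }
  list(xf = grade_axis(-length_um / 2, length_um / 2, nx, fx, strength[1]),
       yf = grade_axis(-w_um / 2, w_um / 2, ny, fy, strength[2]),
       zf = grade_axis(0, h_um, nz, fz, strength[3]))
}

# voxelize a watertight surface onto cell centres
voxelize_obstacle <- function(surface, xc, yc, zc) {
  solid <- array(FALSE, dim = c(length(xc), length(yc), length(zc)))
  bb <- apply(surface$vertices, 2, range)
  ii <- which(xc >= bb[1, 1] & xc <= bb[2, 1])
  jj <- which(yc >= bb[1, 2] & yc <= bb[2, 2])
  kk <- which(zc >= bb[1, 3] & zc <= bb[2, 3])
  if (!length(ii) || !length(jj) || !length(kk)) return(solid)
  G <- expand.grid(x = xc[ii], y = yc[jj], z = zc[kk])
  inside <- .cpp_points_in_mesh(as.matrix(G), surface$vertices, surface$faces)
  solid[ii, jj, kk] <- array(inside, dim = c(length(ii), length(jj), length(kk)))
  solid
}

#' Solve steady incompressible flow in the channel
#'
#' SIMPLE pressure-velocity coupling on a staggered rectilinear grid. The
#' inlet carries the fully developed analytic duct profile, the outlet is a
#' zero-gradient outflow conserving the volumetric flow, and all channel
#' walls and obstacle cells are no-slip. The obstacle is voxelized at the
#' grid resolution (first-order immersed boundary).
#'
#' @param geom a [channel_geometry()].
#' @param obstacle optional watertight [tri_surface] (um coordinates) inside
#'   the domain.
#' @param grid face coordinates from [channel_grid()]; built automatically
#'   (focused on the obstacle) when `NULL`.
#' @param length_um,nx,ny,nz grid parameters when `grid` is `NULL`.
#' @param density_kg_m3 fluid density; defaults to the geometry's, else 1060.
#' @param tol normalized residual tolerance (mass and momentum, scaled by
#'   rho Q and rho Q U_mean).
#' @param max_iter maximum outer iterations.
#' @param alpha_u,alpha_p under-relaxation factors.
#' @param n_sweep_mom,n_sweep_p Gauss-Seidel / SOR sweeps per outer
#'   iteration.
#' @param omega SOR over-relaxation for the pressure correction.
#' @param strict error on non-convergence (the residual history is attached
#'   to the condition); if `FALSE`, return the field with a warning.
#' @return a `flow_field`: staggered and cell-centred velocities (m/s),
#'   pressure (Pa), obstacle mask, grid (um), residual history.
#' @export
solve_steady_flow <- function(geom, obstacle = NULL, grid = NULL,
                              length_um = 600, nx = 48, ny = 36, nz = 24,
                              density_kg_m3 = NULL, tol = 1e-8,
                              max_iter = 4000, alpha_u = 0.7, alpha_p = 0.3,
                              n_sweep_mom = 3, n_sweep_p = 60, omega = 1.2,
                              strict = TRUE) {
  if (is.null(density_kg_m3))
    density_kg_m3 <- if (!is.null(geom$density_kg_m3)) geom$density_kg_m3 else 1060
  if (is.null(grid))
    grid <- channel_grid(geom, length_um = length_um, nx = nx, ny = ny,
                         nz = nz, focus = obstacle)
  xf <- grid$xf; yf <- grid$yf; zf <- grid$zf
  nx <- length(xf) - 1; ny <- length(yf) - 1; nz <- length(zf) - 1
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  yc <- (yf[-1] + yf[-length(yf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2

  solid <- array(FALSE, dim = c(nx, ny, nz))
  if (!is.null(obstacle)) {
    wt <- .cpp_edge_audit(obstacle$faces)
    if (!isTRUE(wt$watertight)) stopf("obstacle surface must be watertight")
    bb <- apply(obstacle$vertices, 2, range)
    if (bb[1, 1] < xf[1] || bb[2, 1] > xf[length(xf)] ||
        bb[1, 2] < yf[1] || bb[2, 2] > yf[length(yf)] ||
        bb[1, 3] < 0 - 1e-9 || bb[2, 3] > zf[length(zf)])
      stopf("obstacle does not fit inside the channel domain")
    solid <- voxelize_obstacle(obstacle, xc, yc, zc)
  }

  uin <- matrix(analytic_duct_velocity(
    geom,
    y_um = rep(yc, times = nz),
    z_um = rep(zc, each = ny)), nrow = ny)
  # rescale so the DISCRETE inlet flux equals Q exactly: the outlet is mass-
  # corrected to Q, so any quadrature error of the sampled profile would
  # otherwise be an irreducible mass imbalance
  area <- outer(diff(yf), diff(zf)) * 1e-12
  uin <- uin * (geom$Q_m3_s / sum(uin * area))

  sol <- .cpp_simple_solve(xf * 1e-6, yf * 1e-6, zf * 1e-6,
                           as.logical(solid), uin,
                           density_kg_m3, geom$mu_Pa_s, geom$Q_m3_s,
                           tol, as.integer(max_iter), alpha_u, alpha_p,
                           as.integer(n_sweep_mom), as.integer(n_sweep_p),
                           omega)
  u <- array(sol$u, dim = c(nx + 1, ny, nz))
  v <- array(sol$v, dim = c(nx, ny + 1, nz))
  w <- array(sol$w, dim = c(nx, ny, nz + 1))
  uc <- (u[-1, , , drop = FALSE] + u[-(nx + 1), , , drop = FALSE]) / 2
  vc <- (v[, -1, , drop = FALSE] + v[, -(ny + 1), , drop = FALSE]) / 2
  wc <- (w[, , -1, drop = FALSE] + w[, , -(nz + 1), drop = FALSE]) / 2
  uc[solid] <- 0; vc[solid] <- 0; wc[solid] <- 0

  field <- structure(list(
    grid = list(xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc),
    u = u, v = v, w = w,
    uc = uc, vc = vc, wc = wc,
    p = array(sol$p, dim = c(nx, ny, nz)),
    solid = solid, uin = uin, geom = geom,
    density_kg_m3 = density_kg_m3,
    residuals = sol$residuals, iterations = sol$iterations,
    converged = sol$converged, obstacle = obstacle),
    class = "flow_field")
  if (!sol$converged) {
    last <- sol$residuals[nrow(sol$residuals), ]
    msg <- sprintf(paste0("flow solver did not converge in %d iterations ",
                          "(final residuals: mass %.2e, momentum %.2e/%.2e/%.2e)"),
                   sol$iterations, last[1], last[2], last[3], last[4])
    if (strict) {
      cond <- structure(class = c("thromboflow_convergence_error", "error",
                                  "condition"),
                        list(message = msg, call = NULL,
                             residuals = sol$residuals))
      stop(cond)
    }
    warning(msg)
  }
  field
}

#' @export
print.flow_field <- function(x, ...) {
  d <- dim(x$uc)
  cat(sprintf("<flow_field> %d x %d x %d cells, %d solid, %s after %d iterations\n",
              d[1], d[2], d[3], sum(x$solid),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Volumetric flux through each cross-section
#'
#' Integrates the axial staggered velocity over every x-face plane; for an
#' incompressible solution all values match the imposed flow rate.
#'
#' @param field a `flow_field`.
#' @return numeric vector (m^3/s), one entry per x-face.
#' @export
cross_section_flux <- function(field) {
  dy <- diff(field$grid$yf) * 1e-6
  dz <- diff(field$grid$zf) * 1e-6
  area <- outer(dy, dz)
  apply(field$u, 1, function(s) sum(s * area))
}

#' Analytic empty-duct flow field
#'
#' The exact fully developed profile sampled on a rectilinear grid in the
#' `flow_field` layout, for tracer tests and desk-scale analyses without an
#' obstacle solve.
#'
#' @param geom a [channel_geometry()].
#' @param length_um,nx,ny,nz domain and grid.
#' @return a `flow_field` (velocities exactly unidirectional).
#' @export
analytic_flow_field <- function(geom, length_um = 2000, nx = 24, ny = 40,
                                nz = 30) {
  grid <- channel_grid(geom, length_um = length_um, nx = nx, ny = ny, nz = nz)
  xf <- grid$xf; yf <- grid$yf; zf <- grid$zf
  xc <- (xf[-1] + xf[-length(xf)]) / 2
  yc <- (yf[-1] + yf[-length(yf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  prof <- matrix(analytic_duct_velocity(
    geom, y_um = rep(yc, times = nz), z_um = rep(zc, each = ny)), nrow = ny)
  uc <- aperm(array(prof, dim = c(ny, nz, nx)), c(3, 1, 2))
  u <- array(0, dim = c(nx + 1, ny, nz))
  for (i in seq_len(nx + 1)) u[i, , ] <- prof
  structure(list(
    grid = list(xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc),
    u = u, v = array(0, dim = c(nx, ny + 1, nz)),
    w = array(0, dim = c(nx, ny, nz + 1)),
    uc = uc, vc = array(0, dim = dim(uc)), wc = array(0, dim = dim(uc)),
    p = array(0, dim = dim(uc)),
    solid = array(FALSE, dim = dim(uc)), uin = prof, geom = geom,
    density_kg_m3 = geom$density_kg_m3,
    residuals = NULL, iterations = 0L, converged = TRUE, obstacle = NULL),
    class = "flow_field")
}

# one-axis cell-centred gradient with no-slip-aware one-sided differences.
# A: (nx,ny,nz) component values; bc_lo: value AT the lower domain face
# (matrix or scalar); bc_hi similarly, or NULL for one-sided (outflow).
grad_axis <- function(A, S, centers, faces, axis, bc_lo = 0, bc_hi = 0) {
  d <- dim(A)
  G <- array(0, dim = d)
  n <- d[axis]
  slab <- function(arr, i) {
    switch(axis, arr[i, , ], arr[, i, ], arr[, , i])
  }
  for (i in seq_len(n)) {
    Ai <- slab(A, i)
    # lower side
    if (i > 1) {
      VL <- slab(A, i - 1); XL <- matrix(centers[i - 1], nrow(Ai), ncol(Ai))
      SL <- slab(S, i - 1)
      VL[SL] <- 0; XL[SL] <- faces[i]
    } else if (!is.null(bc_lo)) {
      VL <- if (is.matrix(bc_lo)) bc_lo else matrix(bc_lo, nrow(Ai), ncol(Ai))
      XL <- matrix(faces[1], nrow(Ai), ncol(Ai))
    } else {
      VL <- Ai; XL <- matrix(centers[i], nrow(Ai), ncol(Ai))
    }
    # upper side
    if (i < n) {
      VR <- slab(A, i + 1); XR <- matrix(centers[i + 1], nrow(Ai), ncol(Ai))
      SR <- slab(S, i + 1)
      VR[SR] <- 0; XR[SR] <- faces[i + 1]
    } else if (!is.null(bc_hi)) {
      VR <- if (is.matrix(bc_hi)) bc_hi else matrix(bc_hi, nrow(Ai), ncol(Ai))
      XR <- matrix(faces[n + 1], nrow(Ai), ncol(Ai))
    } else {
      VR <- Ai; XR <- matrix(centers[i], nrow(Ai), ncol(Ai))
    }
    dx <- XR - XL
    g <- (VR - VL) / ifelse(dx == 0, 1, dx)
    switch(axis, G[i, , ] <- g, G[, i, ] <- g, G[, , i] <- g)
  }
  G
}

#' Local shear-rate field from a solved flow
#'
#' Computes the rate-of-strain tensor D = (grad U + grad U^T)/2 by central
#' differences (one-sided toward no-slip faces at walls, obstacle cells and
#' the inlet/outlet) and the local shear rate gamma = sqrt(2 D:D). For simple
#' shear u = gdot z this returns gdot; for rigid rotation it returns 0.
#'
#' @param field a `flow_field`.
#' @return a `shear_field`: `gamma` (1/s, cell-centred array, 0 inside the
#'   obstacle) and the six independent components of D (1/s).
#' @export
compute_shear_field <- function(field) {
  g <- field$grid
  S <- field$solid
  # convert grid to m so gradients of m/s come out in 1/s
  xc <- g$xc * 1e-6; yc <- g$yc * 1e-6; zc <- g$zc * 1e-6
  xf <- g$xf * 1e-6; yf <- g$yf * 1e-6; zf <- g$zf * 1e-6
  ny <- length(yc); nz <- length(zc)
  uin3 <- field$uin  # (ny x nz) matrix at the inlet face
  dux <- grad_axis(field$uc, S, xc, xf, 1, bc_lo = uin3, bc_hi = NULL)
  dvx <- grad_axis(field$vc, S, xc, xf, 1, bc_lo = 0, bc_hi = NULL)
  dwx <- grad_axis(field$wc, S, xc, xf, 1, bc_lo = 0, bc_hi = NULL)
  duy <- grad_axis(field$uc, S, yc, yf, 2)
  dvy <- grad_axis(field$vc, S, yc, yf, 2)
  dwy <- grad_axis(field$wc, S, yc, yf, 2)
  duz <- grad_axis(field$uc, S, zc, zf, 3)
  dvz <- grad_axis(field$vc, S, zc, zf, 3)
  dwz <- grad_axis(field$wc, S, zc, zf, 3)
  D11 <- dux; D22 <- dvy; D33 <- dwz
  D12 <- 0.5 * (duy + dvx)
  D13 <- 0.5 * (duz + dwx)
  D23 <- 0.5 * (dvz + dwy)
  gamma <- sqrt(2 * (D11^2 + D22^2 + D33^2 + 2 * D12^2 + 2 * D13^2 + 2 * D23^2))
  gamma[S] <- 0
  structure(list(gamma = gamma,
                 D = list(D11 = D11, D22 = D22, D33 = D33,
                          D12 = D12, D13 = D13, D23 = D23),
                 grid = g, solid = S),
            class = "shear_field")
}
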