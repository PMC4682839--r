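#' Growth laws for phantom semi-axes
#'
#' Each growth law returns the multiplicative factor applied to the base
#' semi-axes at time t (factor 1 at t = 0). Rates may be scalars (all axes)
#' or length-3 vectors (per axis a, b, c).
#'
#' @param rate fractional growth rate per second (linear: axis = a0(1+rt);
#'   exponential: axis = a0 exp(rt)).
#' @return a `growth_law` object.
#' @export
growth_linear <- function(rate) {
  rate <- rep_len(rate, 3)
  structure(list(kind = "linear", rate = rate), class = "growth_law")
}

#' @rdname growth_linear
#' @export
growth_none <- function() growth_linear(0)

#' @rdname growth_linear
#' @export
growth_exponential <- function(rate) {
  rate <- rep_len(rate, 3)
  structure(list(kind = "exponential", rate = rate), class = "growth_law")
}

#' @rdname growth_linear
#' @param amplitude asymptotic fractional increase of each semi-axis (the
#'   axis tends to a0 * (1 + amplitude)).
#' @param midpoint time (s) of fastest growth.
#' @export
growth_logistic <- function(amplitude, rate, midpoint) {
  amplitude <- rep_len(amplitude, 3)
  rate <- rep_len(rate, 3)
  midpoint <- rep_len(midpoint, 3)
  structure(list(kind = "logistic", amplitude = amplitude, rate = rate,
                 midpoint = midpoint), class = "growth_law")
}

# per-axis multiplicative factor at time t (vectorised over t: returns 3 x
# length(t) matrix)
growth_factor <- function(law, t) {
  f <- switch(law$kind,
    linear = outer(law$rate, t, function(r, tt) 1 + r * tt),
    exponential = outer(law$rate, t, function(r, tt) exp(r * tt)),
    logistic = {
      s <- function(a, r, m, tt) {
        s0 <- 1 / (1 + exp(r * m))
        1 + a * (1 / (1 + exp(-r * (tt - m))) - s0) / (1 - s0)
      }
      rbind(s(law$amplitude[1], law$rate[1], law$midpoint[1], t),
            s(law$amplitude[2], law$rate[2], law$midpoint[2], t),
            s(law$amplitude[3], law$rate[3], law$midpoint[3], t))
    },
    stopf("unknown growth law '%s'", law$kind))
  matrix(f, nrow = 3)
}

#' Linear growth rate achieving a target volume increase
#'
#' For equal linear growth of the three semi-axes, volume scales as
#' (1 + r t)^3, so a fractional volume increase f over duration T requires
#' r = ((1+f)^(1/3) - 1) / T.
#'
#' @param fraction fractional volume increase (0.12 for 12 percent).
#' @param duration time (s) over which the increase occurs.
#' @return per-axis linear rate (1/s).
#' @export
growth_rate_for_volume_increase <- function(fraction, duration) {
  stopifnot(fraction > -1, duration > 0)
  ((1 + fraction)^(1 / 3) - 1) / duration
}

#' Growing semi-ellipsoid phantom
#'
#' A wall-attached half-ellipsoid x^2/a(t)^2 + y^2/b(t)^2 + z^2/c(t)^2 <= 1,
#' z >= 0, with semi-axes following a growth law. The phantom exposes its
#' exact indicator function, volume and surface at any time, serving as
#' ground truth for reconstruction and time-correction validation.
#'
#' @param a0,b0,c0 base semi-axes (um) along x (flow), y (width), z (height).
#' @param growth a `growth_law` (see [growth_linear()]).
#' @param seed integer seed (only used by lobed variants; kept for a uniform
#'   interface).
#' @return a `phantom` object.
#' @export
make_semi_ellipsoid_phantom <- function(a0, b0, c0, growth = growth_none(),
                                        seed = NULL) {
  if (any(c(a0, b0, c0) <= 0)) stopf("semi-axes must be positive")
  structure(list(a0 = a0, b0 = b0, c0 = c0, growth = growth,
                 lobes = NULL, seed = seed),
            class = "phantom")
}

#' Lobed thrombus-like phantom
#'
#' A semi-ellipsoid with a smooth, seeded angular perturbation of its radial
#' extent: the boundary is rho = 1 + eps * g(phi, theta) in normalised
#' ellipsoidal coordinates, with g a random mixture of azimuthal cosine lobes
#' tapered by sin(theta)^2 so the perturbation vanishes at the apex and the
#' wall contact stays smooth. Because eps < 1 the region remains star-shaped
#' about the origin, hence a single connected component. The default
#' dimensions give a bounding box close to 75 x 12 x 30 um, a typical
#' thrombus size at arterial shear.
#'
#' @inheritParams make_semi_ellipsoid_phantom
#' @param n_lobes number of azimuthal lobes.
#' @param amplitude radial perturbation amplitude (um); must be smaller than
#'   the smallest semi-axis.
#' @param seed integer seed for the lobe phases/weights (reproducible).
#' @return a `phantom` object.
#' @export
make_lobed_phantom <- function(a0 = 37.5, b0 = 6, c0 = 30, n_lobes = 4,
                               amplitude = 1.2, growth = growth_none(),
                               seed = 1) {
  if (any(c(a0, b0, c0) <= 0)) stopf("semi-axes must be positive")
  if (amplitude < 0 || amplitude >= min(a0, b0, c0))
    stopf("lobe amplitude must be in [0, min semi-axis) to avoid self-intersection")
  lobes <- NULL
  if (amplitude > 0 && n_lobes > 0) {
    pars <- with_seed(seed, list(
      phase = runif(n_lobes, 0, 2 * pi),
      weight = runif(n_lobes, 0.5, 1)))
    pars$weight <- pars$weight / sum(pars$weight)
    lobes <- list(n = n_lobes, eps = amplitude / min(a0, b0, c0),
                  phase = pars$phase, weight = pars$weight)
  }
  structure(list(a0 = a0, b0 = b0, c0 = c0, growth = growth,
                 lobes = lobes, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> semi-axes %.1f x %.1f x %.1f um, growth '%s'%s\n",
              x$a0, x$b0, x$c0, x$growth$kind,
              if (is.null(x$lobes)) "" else sprintf(", %d lobes", x$lobes$n)))
  invisible(x)
}

# semi-axes at time t
phantom_axes <- function(ph, t) {
  f <- growth_factor(ph$growth, t)
  c(ph$a0, ph$b0, ph$c0) * f[, 1]
}

# lobe modulation for unit directions (ux, uy, uz in normalised coords)
lobe_modulation <- function(ph, ux, uy, uz) {
  if (is.null(ph$lobes)) return(rep(1, length(ux)))
  phi <- atan2(uy, ux)
  sin2th <- pmax(0, 1 - uz^2)
  g <- 0
  for (j in seq_len(ph$lobes$n))
    g <- g + ph$lobes$weight[j] * cos(j * phi + ph$lobes$phase[j])
  1 + ph$lobes$eps * sin2th * g
}

#' Phantom implicit function and indicator
#'
#' `phantom_field` returns the implicit value m(direction) - rho (positive
#' inside, zero on the boundary); `phantom_inside` the logical indicator
#' (implicit value >= 0 and z >= 0).
#'
#' @param ph a `phantom`.
#' @param x,y,z coordinates (um), recycled to a common length.
#' @param t time (s).
#' @return numeric (field) or logical (indicator) vector.
#' @export
phantom_field <- function(ph, x, y, z, t) {
  ax <- phantom_axes(ph, t)
  xn <- x / ax[1]; yn <- y / ax[2]; zn <- z / ax[3]
  rho <- sqrt(xn^2 + yn^2 + zn^2)
  m <- rep(1, length(rho))
  nz <- rho > 0
  if (!is.null(ph$lobes))
    m[nz] <- lobe_modulation(ph, xn[nz] / rho[nz], yn[nz] / rho[nz],
                             zn[nz] / rho[nz])
  m - rho
}

#' @rdname phantom_field
#' @export
phantom_inside <- function(ph, x, y, z, t) {
  phantom_field(ph, x, y, z, t) >= 0 & z >= 0
}

#' Exact phantom volume at a timepoint
#'
#' The region is star-shaped about the origin, so the volume is the
#' half-space spherical integral of the boundary radius cubed, evaluated by
#' midpoint quadrature in (phi, theta). For a pure semi-ellipsoid this
#' reduces (to quadrature accuracy) to (2/3) pi a b c.
#'
#' @param ph a `phantom`.
#' @param t time (s).
#' @param n quadrature points per angle.
#' @return volume (um^3).
#' @export
phantom_volume <- function(ph, t, n = 400) {
  ax <- phantom_axes(ph, t)
  if (is.null(ph$lobes)) return(2 / 3 * pi * prod(ax))
  dphi <- 2 * pi / n
  dth <- (pi / 2) / n
  phi <- (seq_len(n) - 0.5) * dphi
  th <- (seq_len(n) - 0.5) * dth
  G <- expand.grid(phi = phi, th = th)
  dx <- sin(G$th) * cos(G$phi); dy <- sin(G$th) * sin(G$phi); dz <- cos(G$th)
  q <- sqrt((dx / ax[1])^2 + (dy / ax[2])^2 + (dz / ax[3])^2)
  m <- lobe_modulation(ph, dx / ax[1] / q, dy / ax[2] / q, dz / ax[3] / q)
  smax <- m / q
  sum(smax^3 / 3 * sin(G$th)) * dphi * dth
}

#' Exact phantom surface at a timepoint
#'
#' Iso-surface of the implicit function on a fine grid, capped at the wall
#' plane z = 0. This is the reconstruction-free ground truth.
#'
#' @param ph a `phantom`.
#' @param t time (s).
#' @param resolution grid step (um).
#' @return a watertight [tri_surface].
#' @export
phantom_surface <- function(ph, t, resolution = 0.25) {
  ax <- phantom_axes(ph, t)
  marg <- 1 + if (is.null(ph$lobes)) 0 else ph$lobes$eps
  xr <- ax[1] * marg + 2 * resolution
  yr <- ax[2] * marg + 2 * resolution
  zr <- ax[3] * marg + 2 * resolution
  xs <- seq(-xr, xr, by = resolution)
  ys <- seq(-yr, yr, by = resolution)
  zs <- c(-resolution, seq(0, zr, by = resolution))
  G <- expand.grid(x = xs, y = ys, z = zs)
  f <- phantom_field(ph, G$x, G$y, G$z, t)
  f[G$z < 0] <- -1e3    # hard cap below the wall
  vol <- array(f, dim = c(length(xs), length(ys), length(zs)))
  m <- .cpp_marching_tetrahedra(vol, xs, ys, zs, 0)
  m$vertices[m$vertices[, 3] < 1e-6, 3] <- 0
  tri_surface(m$vertices, m$faces, t_s = t, floor_z = 0)
}

#' Confocal acquisition schedule
#'
#' Timing and sampling parameters of the emulated confocal microscope: each
#' stack is scanned bottom-up over `scan_s` seconds followed by `transfer_s`
#' seconds of data transfer, so the stack period is their sum; slice k of
#' stack m is stamped t = m (scan + transfer) + k scan / n_slices.
#'
#' @param n_slices slices per stack (including `guard_slices` blank slices
#'   recorded below the wall, emulating scanning from below the interface).
#' @param n_stacks number of consecutive stacks.
#' @param slice_um slice thickness (um).
#' @param pixel_um pixel size (um/pixel).
#' @param width_px,height_px image size (pixels; x and y).
#' @param scan_s scan duration per stack (s).
#' @param transfer_s data-transfer dead time per stack (s).
#' @param bit_depth native bit depth of the detector.
#' @param guard_slices blank slices below z = 0.
#' @return an `acquisition_schedule` object.
#' @export
acquisition_schedule <- function(n_slices, n_stacks = 3, slice_um = 0.5,
                                 pixel_um = 0.31, width_px = 512,
                                 height_px = 512, scan_s = 1.2,
                                 transfer_s = 2.3, bit_depth = 12,
                                 guard_slices = 2) {
  stopifnot(n_slices > guard_slices, n_stacks >= 1, slice_um > 0,
            pixel_um > 0, scan_s > 0, transfer_s > 0, bit_depth >= 8)
  structure(list(n_slices = as.integer(n_slices),
                 n_stacks = as.integer(n_stacks),
                 slice_um = slice_um, pixel_um = pixel_um,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 scan_s = scan_s, transfer_s = transfer_s,
                 bit_depth = as.integer(bit_depth),
                 guard_slices = as.integer(guard_slices),
                 slice_dt_s = scan_s / n_slices,
                 period_s = scan_s + transfer_s),
            class = "acquisition_schedule")
}

# z positions (um) of the slices of a stack
schedule_z <- function(sch) (seq_len(sch$n_slices) - 1 - sch$guard_slices) * sch$slice_um

#' Render one confocal optical section of a phantom
#'
#' Pixels whose centres fall inside the phantom cross-section at height z and
#' time t receive the foreground intensity; the background is 0. Optional
#' seeded Gaussian and salt-and-pepper noise.
#'
#' @param ph a `phantom`.
#' @param z slice height (um).
#' @param t acquisition time (s).
#' @param schedule an [acquisition_schedule()].
#' @param foreground foreground intensity (default 80 percent of full scale).
#' @param noise `NULL` (noiseless) or
#'   `list(gaussian_sd =, salt_pepper =, seed =)`.
#' @return integer intensity matrix (rows = y, columns = x).
#' @export
render_slice <- function(ph, z, t, schedule, foreground = NULL, noise = NULL) {
  maxv <- 2^schedule$bit_depth - 1
  if (is.null(foreground)) foreground <- round(0.8 * maxv)
  xc <- px_coords(schedule$width_px, schedule$pixel_um)
  yc <- px_coords(schedule$height_px, schedule$pixel_um)
  img <- matrix(0, nrow = schedule$height_px, ncol = schedule$width_px)
  if (z >= 0) {
    G <- expand.grid(y = yc, x = xc)
    inside <- phantom_inside(ph, G$x, G$y, rep(z, nrow(G)), t)
    img[inside] <- foreground
  }
  if (!is.null(noise)) {
    img <- with_seed(noise$seed, {
      n <- length(img)
      if (!is.null(noise$gaussian_sd) && noise$gaussian_sd > 0)
        img <- img + rnorm(n, 0, noise$gaussian_sd)
      if (!is.null(noise$salt_pepper) && noise$salt_pepper > 0) {
        hit <- runif(n) < noise$salt_pepper
        img[hit] <- ifelse(runif(sum(hit)) < 0.5, 0, maxv)
      }
      img
    })
  }
  img <- round(pmin(pmax(img, 0), maxv))
  storage.mode(img) <- "integer"
  img
}

#' Acquire time-skewed z-stacks of a growing phantom
#'
#' Emulates the confocal acquisition process: each stack is scanned
#' bottom-up, each slice rendered from the phantom at its own timestamp, so a
#' growing phantom produces time-skewed stacks; per-slice z and t are
#' recorded as metadata.
#'
#' @param ph a `phantom`.
#' @param schedule an [acquisition_schedule()].
#' @param foreground,noise passed to [render_slice()] (noise seeds are drawn
#'   per slice from `noise$seed` for reproducibility).
#' @return list of `zstack` objects.
#' @export
acquire_zstacks <- function(ph, schedule, foreground = NULL, noise = NULL) {
  zpos <- schedule_z(schedule)
  stacks <- vector("list", schedule$n_stacks)
  for (m in seq_len(schedule$n_stacks) - 1L) {
    t0 <- m * schedule$period_s
    ts <- t0 + (seq_len(schedule$n_slices) - 1) * schedule$slice_dt_s
    slices <- vector("list", schedule$n_slices)
    for (k in seq_len(schedule$n_slices)) {
      nz <- noise
      if (!is.null(nz) && !is.null(nz$seed))
        nz$seed <- nz$seed + 1000L * m + k
      slices[[k]] <- render_slice(ph, zpos[k], ts[k], schedule,
                                  foreground = foreground, noise = nz)
    }
    stacks[[m + 1L]] <- zstack(slices, z_um = zpos, t_s = ts,
                               pixel_um = schedule$pixel_um,
                               bit_depth = schedule$bit_depth,
                               stack_index = m + 1L)
  }
  stacks
}

#' Confocal z-stack container
#'
#' @param slices list of intensity matrices (rows = y, columns = x), ordered
#'   bottom-up.
#' @param z_um per-slice z position (um), increasing.
#' @param t_s per-slice acquisition timestamp (s), non-decreasing.
#' @param pixel_um pixel size (um/pixel).
#' @param bit_depth intensity bit depth.
#' @param stack_index 1-based index in the acquisition series.
#' @return a `zstack` object.
#' @export
zstack <- function(slices, z_um, t_s, pixel_um, bit_depth = 12,
                   stack_index = 1L) {
  stopifnot(length(slices) == length(z_um), length(z_um) == length(t_s),
            pixel_um > 0, all(is.finite(z_um)), all(is.finite(t_s)))
  if (is.unsorted(z_um, strictly = TRUE)) stopf("slices must be sorted by increasing z")
  if (is.unsorted(t_s)) stopf("slice timestamps must be non-decreasing")
  structure(list(slices = slices, z_um = z_um, t_s = t_s,
                 pixel_um = pixel_um, bit_depth = as.integer(bit_depth),
                 stack_index = as.integer(stack_index)),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("<zstack %d> %d slices %dx%d px, z %.1f..%.1f um, t %.2f..%.2f s\n",
              x$stack_index, length(x$slices), nrow(x$slices[[1]]),
              ncol(x$slices[[1]]), min(x$z_um), max(x$z_um),
              min(x$t_s), max(x$t_s)))
  invisible(x)
}
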