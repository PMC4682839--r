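# shared fixtures, all generated in code

# free-standing sphere mesh from the implicit function
sphere_surface <- function(r, res = 0.5, t_s = NA_real_) {
  xs <- seq(-r - 3, r + 3, by = res)
  G <- expand.grid(x = xs, y = xs, z = xs)
  f <- r - sqrt(G$x^2 + G$y^2 + G$z^2)
  m <- thromboflow:::.cpp_marching_tetrahedra(
    array(f, c(length(xs), length(xs), length(xs))), xs, xs, xs, 0)
  tri_surface(m$vertices, m$faces, t_s = t_s)
}

# sphere with a superposed spherical bump (union of implicits)
bumpy_sphere_surface <- function(r, bump_r, bump_c, res = 0.5, t_s = NA_real_) {
  xs <- seq(-r - bump_r - 3, r + bump_r + 3, by = res)
  G <- expand.grid(x = xs, y = xs, z = xs)
  f <- pmax(r - sqrt(G$x^2 + G$y^2 + G$z^2),
            bump_r - sqrt((G$x - bump_c[1])^2 + (G$y - bump_c[2])^2 +
                          (G$z - bump_c[3])^2))
  m <- thromboflow:::.cpp_marching_tetrahedra(
    array(f, c(length(xs), length(xs), length(xs))), xs, xs, xs, 0)
  tri_surface(m$vertices, m$faces, t_s = t_s)
}

circle_poly <- function(r, cx = 0, cy = 0, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# segmented stack of a cylinder with alternating per-slice radius (ripple)
cylinder_stack <- function(r1 = 10, r2 = 10.6, n = 40, px = 0.31, wpx = 90) {
  xc <- (seq_len(wpx) - (wpx + 1) / 2) * px
  G <- expand.grid(y = xc, x = xc)
  masks <- lapply(seq_len(n), function(k) {
    r <- if (k %% 2 == 0) r2 else r1
    matrix(G$x^2 + G$y^2 <= r^2, wpx, wpx)
  })
  structure(list(masks = masks, z_um = (seq_len(n) - 1) * 0.5,
                 t_s = numeric(n), pixel_um = px, threshold = 100,
                 stack_index = 1L, width_px = wpx, height_px = wpx),
            class = "segmented_stack")
}

# right trapezoidal prism: base 30, top 15 (slant in x-z), height 20, depth 30
trapezoid_stack <- function(n = 41, px = 0.31, wpx = 140) {
  xc <- (seq_len(wpx) - (wpx + 1) / 2) * px
  G <- expand.grid(y = xc, x = xc)
  masks <- lapply(seq_len(n), function(k) {
    zz <- (k - 1) * 0.5
    xmax <- 15 - (zz / 20) * 15
    matrix(G$x >= -15 & G$x <= xmax & abs(G$y) <= 15 & zz <= 20, wpx, wpx)
  })
  structure(list(masks = masks, z_um = (seq_len(n) - 1) * 0.5,
                 t_s = numeric(n), pixel_um = px, threshold = 100,
                 stack_index = 1L, width_px = wpx, height_px = wpx),
            class = "segmented_stack")
}

# hemisphere acquisition (static) for reconstruction round trips
hemisphere_stack <- function(r = 15, slice_um = 0.5, pixel_um = 0.93) {
  ph <- make_semi_ellipsoid_phantom(r, r, r)
  n <- ceiling(r / slice_um) + 5
  sch <- acquisition_schedule(n_slices = n, n_stacks = 1, slice_um = slice_um,
                              pixel_um = pixel_um,
                              width_px = ceiling(2.4 * r / pixel_um),
                              height_px = ceiling(2.4 * r / pixel_um))
  list(phantom = ph, stack = acquire_zstacks(ph, sch)[[1]])
}

# min distance from points to a polygon boundary (for morph symmetry checks)
points_polygon_distance <- function(pts, poly) {
  m <- nrow(poly)
  d2 <- rep(Inf, nrow(pts))
  for (a in seq_len(m)) {
    b <- if (a == m) 1L else a + 1L
    ex <- poly[b, 1] - poly[a, 1]; ey <- poly[b, 2] - poly[a, 2]
    len2 <- ex^2 + ey^2
    t <- ((pts[, 1] - poly[a, 1]) * ex + (pts[, 2] - poly[a, 2]) * ey) /
      max(len2, 1e-30)
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (poly[a, 1] + t * ex)
    dy <- pts[, 2] - (poly[a, 2] + t * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

# memoized desk-scale obstacle flow solve shared by flow/lagrangian/acceptance
.fixture_env <- new.env(parent = emptyenv())

demo_obstacle_case <- function() {
  if (!is.null(.fixture_env$case)) return(.fixture_env$case)
  geom <- channel_geometry(density_kg_m3 = 940)
  ph <- make_lobed_phantom(seed = 7)
  surf <- phantom_surface(ph, 0, resolution = 1)
  field <- solve_steady_flow(geom, obstacle = surf, length_um = 500,
                             nx = 42, ny = 40, nz = 22, tol = 1e-6,
                             max_iter = 4000)
  shear <- compute_shear_field(field)
  seeds <- seed_surface(surf, field, offset = 1)
  .fixture_env$case <- list(geom = geom, phantom = ph, surface = surf,
                            field = field, shear = shear, seeds = seeds)
  .fixture_env$case
}

# synthetic cell-centred fields on a uniform grid (for shear-convention tests)
synthetic_field <- function(ufun, vfun, wfun, nx = 8, ny = 10, nz = 12,
                            L = c(100, 100, 100)) {
  xf <- seq(0, L[1], length.out = nx + 1)
  yf <- seq(-L[2] / 2, L[2] / 2, length.out = ny + 1)
  zf <- seq(0, L[3], length.out = nz + 1)
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2
  yc <- (yf[-1] + yf[-(ny + 1)]) / 2
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2
  G <- expand.grid(x = xc, y = yc, z = zc)
  shape <- c(nx, ny, nz)
  uin <- matrix(ufun(0, rep(yc, nz), rep(zc, each = ny)), ny, nz)
  structure(list(
    grid = list(xf = xf, yf = yf, zf = zf, xc = xc, yc = yc, zc = zc),
    uc = array(ufun(G$x, G$y, G$z), shape),
    vc = array(vfun(G$x, G$y, G$z), shape),
    wc = array(wfun(G$x, G$y, G$z), shape),
    u = NULL, v = NULL, w = NULL, p = array(0, shape),
    solid = array(FALSE, shape), uin = uin,
    geom = NULL, residuals = NULL, iterations = 0L, converged = TRUE,
    obstacle = NULL), class = "flow_field")
}
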