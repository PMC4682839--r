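test_that("channel-derived quantities match their closed forms", {
  geom <- channel_geometry()  # 2 x 0.2 mm, 1.44 ml/min, 2.8 cP
  expect_equal(nominal_wall_shear(geom), 1800)
  expect_equal(nominal_wall_shear(channel_geometry(flow_ml_min = 0)), 0)
  expect_equal(nominal_wall_shear(channel_geometry(flow_ml_min = 2.88)), 3600)

  expect_equal(round(hydraulic_diameter(geom), 2), 0.36)
  expect_equal(hydraulic_diameter(channel_geometry(width_mm = 1, height_mm = 1)), 1)
  expect_equal(aspect_ratio(geom), 0.1)

  expect_error(reynolds_number(geom), "density")
  expect_equal(reynolds_number(geom, 940), 7.3, tolerance = 0.005)
  expect_error(channel_geometry(width_mm = 0.1, height_mm = 0.2), "h <= w")
})

test_that("the analytic duct profile is exact at walls and integrates to Q", {
  geom <- channel_geometry()
  expect_equal(analytic_duct_velocity(geom, 0, 0), 0, tolerance = 1e-10)
  expect_equal(analytic_duct_velocity(geom, 1000, 100), 0, tolerance = 1e-8)
  expect_error(analytic_duct_velocity(geom, 0, 300), "outside")

  ny <- 400; nz <- 200
  yq <- ((seq_len(ny) - 0.5) / ny - 0.5) * 2000
  zq <- (seq_len(nz) - 0.5) / nz * 200
  G <- expand.grid(y = yq, z = zq)
  Qnum <- sum(analytic_duct_velocity(geom, G$y, G$z)) *
    (2000e-6 / ny) * (200e-6 / nz)
  expect_lt(abs(Qnum / geom$Q_m3_s - 1), 0.001)

  # parallel-plate limit w >> h: centerline velocity -> (3/2) Q/(w h)
  wide <- channel_geometry(width_mm = 200, height_mm = 0.2)
  ucl <- analytic_duct_velocity(wide, 0, 100)
  expect_lt(abs(ucl / (1.5 * wide$Q_m3_s / (wide$w_m * wide$h_m)) - 1), 0.005)
})

test_that("shear-field convention: simple shear recovers the rate, rotation gives zero", {
  gd <- 50  # 1/s when coordinates are um and velocity sampled as m/s * 1e... use direct
  # u = gd * z (velocity in m/s with z in m -> build with z_um * 1e-6)
  f1 <- synthetic_field(function(x, y, z) gd * z * 1e-6,
                        function(x, y, z) 0,
                        function(x, y, z) 0)
  g1 <- compute_shear_field(f1)$gamma
  interior <- g1[2:7, 2:9, 2:11]
  expect_equal(max(abs(interior - gd)), 0, tolerance = 1e-9)

  om <- 30
  f2 <- synthetic_field(function(x, y, z) -om * y * 1e-6,
                        function(x, y, z) om * (x - 50) * 1e-6,
                        function(x, y, z) 0)
  g2 <- compute_shear_field(f2)$gamma
  expect_lt(max(abs(g2[2:7, 2:9, 2:11])), 1e-9 * om)
})

test_that("the empty-channel solve reproduces the analytic duct solution", {
  geom <- channel_geometry()
  f <- solve_steady_flow(geom, length_um = 400, nx = 8, ny = 36, nz = 24,
                         tol = 1e-6, max_iter = 2000)
  expect_true(f$converged)
  g <- f$grid
  jc <- which.min(abs(g$yc)); kc <- which.min(abs(g$zc - 100))
  uan <- analytic_duct_velocity(geom, g$yc[jc], g$zc[kc])
  expect_lt(abs(f$uc[4, jc, kc] / uan - 1), 0.03)

  flux <- cross_section_flux(f)
  expect_lt(max(abs(flux / geom$Q_m3_s - 1)), 0.005)

  # symmetric about the mid-width plane
  expect_lt(max(abs(f$uc - f$uc[, rev(seq_len(dim(f$uc)[2])), ])),
            1e-4 * max(f$uc))

  sh <- compute_shear_field(f)
  gan <- analytic_duct_shear(geom, g$yc[jc], g$zc[1])
  expect_lt(abs(sh$gamma[4, jc, 1] / gan - 1), 0.05)
})

test_that("solver errors are raised for invalid obstacles", {
  geom <- channel_geometry()
  tall <- sphere_surface(6, res = 0.75)
  tall$vertices[, 3] <- tall$vertices[, 3] + 300  # pokes out of the 200 um channel
  expect_error(solve_steady_flow(geom, obstacle = tall, nx = 6, ny = 8, nz = 6),
               "fit inside")
  open_mesh <- sphere_surface(6, res = 0.75)
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(solve_steady_flow(geom, obstacle = open_mesh, nx = 6, ny = 8,
                                 nz = 6), "watertight")
})
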