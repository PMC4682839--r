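test_that("semi-ellipsoid phantom volume matches the closed form and growth laws", {
  ph <- make_semi_ellipsoid_phantom(15, 15, 15)
  expect_equal(phantom_volume(ph, 0), 2 / 3 * pi * 15^3)
  expect_equal(phantom_volume(ph, 100), phantom_volume(ph, 0))  # zero growth

  # linear 1 %/s per axis over 3.5 s: volume ratio = (a b c)(t)/(a0 b0 c0)
  ph2 <- make_semi_ellipsoid_phantom(15, 15, 15, growth = growth_linear(0.01))
  expect_equal(phantom_volume(ph2, 3.5) / phantom_volume(ph2, 0),
               (1 + 0.01 * 3.5)^3, tolerance = 1e-10)

  # rate configured to hit a 12 % volume increase over one stack acquisition
  r <- growth_rate_for_volume_increase(0.12, 3.5)
  ph3 <- make_semi_ellipsoid_phantom(15, 15, 15, growth = growth_linear(r))
  expect_equal(phantom_volume(ph3, 3.5) / phantom_volume(ph3, 0), 1.12,
               tolerance = 1e-10)

  expect_error(make_semi_ellipsoid_phantom(-1, 5, 5), "positive")
})

test_that("lobed phantom is a seeded, bounded perturbation of the ellipsoid", {
  # amplitude 0 reduces to the plain semi-ellipsoid
  p0 <- make_lobed_phantom(20, 6, 10, amplitude = 0, seed = 4)
  pe <- make_semi_ellipsoid_phantom(20, 6, 10)
  x <- runif(200, -20, 20); y <- runif(200, -6, 6); z <- runif(200, 0, 10)
  expect_equal(phantom_field(p0, x, y, z, 0), phantom_field(pe, x, y, z, 0))

  # default preset: bounding box close to 75 x 12 x 30 um (within 10 %)
  met <- surface_metrics(phantom_surface(make_lobed_phantom(seed = 1), 0,
                                         resolution = 0.8))
  expect_lt(abs(met$length_um / 75 - 1), 0.10)
  expect_lt(abs(met$width_um / 12 - 1), 0.10)
  expect_lt(abs(met$height_um / 30 - 1), 0.10)

  # determinism: identical seed -> identical rendering; different seed differs
  sch <- acquisition_schedule(n_slices = 8, n_stacks = 1, width_px = 60,
                              height_px = 60, pixel_um = 1.5)
  s1 <- render_slice(make_lobed_phantom(seed = 11), 5, 0, sch)
  s2 <- render_slice(make_lobed_phantom(seed = 11), 5, 0, sch)
  s3 <- render_slice(make_lobed_phantom(seed = 12), 5, 0, sch)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))

  expect_error(make_lobed_phantom(20, 6, 10, amplitude = 7), "amplitude")
})

test_that("rendered optical sections match analytic cross-sections", {
  ph <- make_semi_ellipsoid_phantom(15, 12, 10)
  sch <- acquisition_schedule(n_slices = 24, n_stacks = 1, width_px = 110,
                              height_px = 110, pixel_um = 0.31)
  # field of view: 512 px at 0.31 um/px covers ~158.7 um
  expect_equal(512 * 0.31, 158.72)

  expect_true(all(render_slice(ph, 11, 0, sch) == 0))  # above the apex

  img <- render_slice(ph, 5, 0, sch)
  area_px <- sum(img > 0) * sch$pixel_um^2
  s <- sqrt(1 - (5 / 10)^2)
  expect_lt(abs(area_px / (pi * 15 * s * 12 * s) - 1), 0.02)
})

test_that("acquisition produces bottom-up time-skewed stacks with exact timing", {
  ph <- make_semi_ellipsoid_phantom(10, 10, 8)
  sch <- acquisition_schedule(n_slices = 20, n_stacks = 3, width_px = 50,
                              height_px = 50, pixel_um = 0.62)
  expect_equal(sch$period_s, 3.5)   # 1.2 s scan + 2.3 s transfer
  stacks <- acquire_zstacks(ph, sch)
  expect_length(stacks, 3)

  # timestamps: strictly increasing within a stack, uniform slice increment,
  # exactly the transfer time between stacks' last/first slices
  for (s in stacks) expect_true(all(diff(s$t_s) > 0))
  expect_equal(unique(round(diff(stacks[[1]]$t_s), 12)), sch$scan_s / 20)
  gap <- stacks[[2]]$t_s[1] - utils::tail(stacks[[1]]$t_s, 1)
  expect_equal(gap, sch$transfer_s + sch$scan_s / 20)

  # static phantom: all stacks pixel-identical
  expect_identical(stacks[[1]]$slices, stacks[[2]]$slices)
  expect_identical(stacks[[2]]$slices, stacks[[3]]$slices)
})

test_that("growing phantom stacks show the bottom-deficit/top-surplus skew", {
  r <- growth_rate_for_volume_increase(0.12, 3.5)
  ph <- make_semi_ellipsoid_phantom(12, 12, 12, growth = growth_linear(r))
  sch <- acquisition_schedule(n_slices = 32, n_stacks = 1, width_px = 60,
                              height_px = 60, pixel_um = 0.62)
  st <- acquire_zstacks(ph, sch)[[1]]
  t_mid <- mean(range(st$t_s))
  ref <- vapply(seq_along(st$z_um), function(k)
    sum(render_slice(ph, st$z_um[k], t_mid, sch) > 0), numeric(1))
  acq <- vapply(st$slices, function(s) sum(s > 0), numeric(1))
  sel <- ref > 50
  diffs <- (acq - ref)[sel]
  z <- st$z_um[sel]
  expect_true(all(diffs[z < 4] <= 0))   # acquired before t_mid: smaller
  expect_true(all(diffs[z > 8] >= 0))   # acquired after t_mid: larger
})
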