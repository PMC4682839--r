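test_that("signed-distance morphing matches the dense interpolation oracle", {
  px <- 0.31
  # identical contours: every intermediate equals the input
  mp <- morph_pair(list(circle_poly(5)), list(circle_poly(5)), 2, px)
  for (k in 1:2) {
    r <- sqrt(rowSums(mp$contours[[k]][[1]]^2))
    expect_lt(max(abs(r - 5)), 0.02)
  }

  # concentric circles 5 -> 10: midpoint is a circle of radius 7.5 (within 1%)
  mp2 <- morph_pair(list(circle_poly(5)), list(circle_poly(10)), 1, px)
  r2 <- sqrt(rowSums(mp2$contours[[1]][[1]]^2))
  expect_lt(max(abs(r2 - 7.5)) / 7.5, 0.01)

  # translation by 4 um: midpoint centred at 2 um (within 0.1 um)
  mp3 <- morph_pair(list(circle_poly(5)), list(circle_poly(5, cx = 4)), 1, px)
  ctr <- colMeans(mp3$contours[[1]][[1]])
  expect_lt(abs(ctr[1] - 2), 0.1)
  expect_lt(abs(ctr[2]), 0.1)

  expect_error(morph_pair(list(circle_poly(5)[c(1, 1, 1), ]),
                          list(circle_poly(5)), 1, px), "degenerate")
})

test_that("morphing is symmetric and consistent at its endpoints", {
  px <- 0.31
  c1 <- list(circle_poly(4, cx = -1))
  c2 <- list(circle_poly(8, cx = 2))
  n <- 3
  fwd <- morph_pair(c1, c2, n, px)
  bwd <- morph_pair(c2, c1, n, px)
  for (k in seq_len(n)) {
    a <- fwd$contours[[k]][[1]]
    b <- bwd$contours[[n + 1 - k]][[1]]     # parameter 1 - s
    expect_lt(max(points_polygon_distance(a, b)), 0.5 * px)
  }
  # parameter ~1 reproduces contour_t2 within half a pixel
  near1 <- morph_pair(c1, c2, 99, px)$contours[[99]][[1]]
  expect_lt(max(points_polygon_distance(near1, c2[[1]])), 0.5 * px)
})

test_that("intermediate areas are monotone for nested contours and grow from empty", {
  px <- 0.31
  mp <- morph_pair(list(circle_poly(3)), list(circle_poly(9)), 7, px)
  areas <- vapply(mp$contours, function(cs)
    sum(vapply(cs, function(p) abs(thromboflow:::polygon_area(p)), numeric(1))),
    numeric(1))
  expect_true(all(diff(areas) > 0))

  # appearance from empty: inflation from the collapse point
  mp2 <- morph_pair(list(), list(circle_poly(5, cx = 3, cy = -2)), 4, px)
  r <- vapply(mp2$contours, function(cs)
    mean(sqrt((cs[[1]][, 1] - 3)^2 + (cs[[1]][, 2] + 2)^2)), numeric(1))
  expect_equal(r, 5 * mp2$s, tolerance = 0.05)
})

test_that("intermediate frame times are linear in the morph parameter", {
  expect_equal(intermediate_times(10, 12, 1), 11)
  expect_equal(intermediate_times(0, 4, 3), c(1, 2, 3))
  expect_error(intermediate_times(4, 4, 1), "strictly increasing")

  ph <- make_semi_ellipsoid_phantom(8, 8, 6)
  sch <- acquisition_schedule(n_slices = 16, n_stacks = 2, width_px = 40,
                              height_px = 40, pixel_um = 0.62)
  tl <- contour_timeline(acquire_zstacks(ph, sch), increment_s = 0.5)
  ft <- frame_times(tl, 5)
  # acquired frames keep their metadata times exactly
  tacq <- vapply(tl$levels[[5]]$frames, `[[`, numeric(1), "t")
  expect_true(all(tacq %in% ft))
  expect_true(all(diff(ft) > 0))
  expect_lte(max(diff(ft)), 0.5 + 1e-12)
})

test_that("instantaneous resampling picks nearest frames inside the correctable window", {
  r <- growth_rate_for_volume_increase(0.12, 3.5)
  ph <- make_semi_ellipsoid_phantom(10, 10, 9, growth = growth_linear(r))
  sch <- acquisition_schedule(n_slices = 24, n_stacks = 3, width_px = 56,
                              height_px = 56, pixel_um = 0.62)
  stacks <- acquire_zstacks(ph, sch)
  tl <- contour_timeline(stacks, increment_s = 0.06)

  expect_error(sample_instantaneous(tl, 0.5), "correctable window")
  expect_error(sample_instantaneous(tl, 50), "correctable window")

  t_star <- 3.5 + 0.6
  inst <- sample_instantaneous(tl, t_star)
  delta <- 0.06
  expect_lte(inst$delta_t_span, 2 * delta)             # nearest-selection bound
  expect_true(all(abs(inst$t_selected - t_star) <= delta + 1e-9))

  # static phantom: the instantaneous stack equals any acquired stack
  ph0 <- make_semi_ellipsoid_phantom(10, 10, 9)
  st0 <- acquire_zstacks(ph0, sch)
  tl0 <- contour_timeline(st0, increment_s = 0.06)
  inst0 <- sample_instantaneous(tl0, t_star)
  seg0 <- segment_stack(st0[[2]])
  expect_identical(inst0$masks, seg0$masks)
  expect_gt(inst0$delta_t_span, 0)   # frame-time spread is still reported
})

test_that("static time-corrected surface equals the direct reconstruction", {
  ph <- make_semi_ellipsoid_phantom(10, 10, 9)
  sch <- acquisition_schedule(n_slices = 24, n_stacks = 3, width_px = 56,
                              height_px = 56, pixel_um = 0.62)
  stacks <- acquire_zstacks(ph, sch)
  tc <- time_corrected_surface(stacks, 4.1)
  direct <- build_surface(stacks[[2]])
  expect_lt(abs(mesh_volume(tc) / mesh_volume(direct) - 1), 0.005)
  expect_equal(tc$t_s, 4.1)
})
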