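test_that("concentric spheres give uniform signed distances of the radius change", {
  s10 <- sphere_surface(10, res = 0.8, t_s = 0)
  s11 <- sphere_surface(11, res = 0.8, t_s = 1)
  s9 <- sphere_surface(9, res = 0.8, t_s = 1)

  gm <- growth_map(s10, s11)
  expect_true(all(gm$valid))
  expect_equal(mean(gm$distance), 1, tolerance = 0.01)
  expect_lt(max(abs(gm$distance - 1)), 0.05)

  gm2 <- growth_map(s10, s9)
  expect_equal(mean(gm2$distance), -1, tolerance = 0.01)
  expect_lt(max(abs(gm2$distance + 1)), 0.05)

  # identical surfaces: all distances zero
  s10b <- s10; s10b$t_s <- 1
  gm0 <- growth_map(s10, s10b)
  expect_lt(max(abs(gm0$distance)), 1e-9)

  # antisymmetry under argument swap (smooth convex fixtures)
  s11e <- s11; s11e$t_s <- 0
  s10l <- s10; s10l$t_s <- 1
  gswap <- growth_map(s11e, s10l)
  expect_equal(mean(gswap$distance), -1, tolerance = 0.05)

  expect_error(growth_map(s10, s9 |> (\(s) { s$t_s <- -1; s })()), "later")
  open_mesh <- s10
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(growth_map(open_mesh, s11), "watertight")
})

test_that("a localized bump is recovered with the constructed height", {
  s10 <- sphere_surface(10, res = 0.7, t_s = 0)
  bump <- bumpy_sphere_surface(10, bump_r = 3, bump_c = c(9.5, 0, 0), res = 0.7, t_s = 1)
  gm <- growth_map(s10, bump)
  d <- gm$distance
  expect_lt(abs(max(d, na.rm = TRUE) / 2.5 - 1), 0.05)   # 9.5 + 3 - 10
  expect_gt(mean(abs(d) < 0.05, na.rm = TRUE), 0.9)       # confined footprint
  # positive values confined near the bump axis
  grown <- which(d > 0.5)
  expect_true(all(s10$vertices[grown, 1] > 5))
})

test_that("growth classification and statistics integrate the map correctly", {
  s10 <- sphere_surface(10, res = 0.8, t_s = 0)
  s11 <- sphere_surface(11, res = 0.8, t_s = 1)
  gm <- growth_map(s10, s11)
  expect_true(all(classify_growth(gm, 0.5) == "growth"))

  s10b <- s10; s10b$t_s <- 1
  gm0 <- growth_map(s10, s10b)
  expect_true(all(classify_growth(gm0) == "neutral"))
  st0 <- growth_stats(gm0)
  expect_equal(st0$mean_um, 0)
  expect_equal(st0$net_volume_estimate_um3, 0)
  expect_equal(st0$exact_volume_change_um3, 0)
  expect_equal(st0$lost_area_um2, 0)

  st <- growth_stats(gm)
  shell <- 4 / 3 * pi * (11^3 - 10^3)
  expect_lt(abs(st$net_volume_estimate_um3 / shell - 1), 0.05)
  # exact difference equals the surface_metrics volumes to machine precision
  expect_equal(st$exact_volume_change_um3,
               surface_metrics(s11)$volume_um3 - surface_metrics(s10)$volume_um3)
})

test_that("the volume estimate converges toward the exact difference under refinement", {
  errs <- vapply(c(1.2, 0.8), function(res) {
    a <- sphere_surface(10, res = res, t_s = 0)
    b <- sphere_surface(11, res = res, t_s = 1)
    st <- growth_stats(growth_map(a, b))
    abs(st$net_volume_estimate_um3 - st$exact_volume_change_um3)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("separate components are paired and unpaired ones flagged embolized", {
  s_a0 <- sphere_surface(5, res = 0.4, t_s = NA)
  # two components at t1: one grows in place, one disappears by t2
  shift <- function(s, dx) { s$vertices[, 1] <- s$vertices[, 1] + dx; s }
  two <- tri_surface(rbind(s_a0$vertices, shift(s_a0, 40)$vertices),
                     rbind(s_a0$faces, s_a0$faces + nrow(s_a0$vertices)),
                     t_s = 0)
  later <- sphere_surface(6, res = 0.4, t_s = 1)
  gm <- growth_map(two, later)
  first <- seq_len(nrow(s_a0$vertices))
  expect_equal(mean(gm$distance[first]), 1, tolerance = 0.02)
  expect_true(all(gm$status[-first] == "embolized"))
  expect_true(all(classify_growth(gm)[-first] == "loss"))
})
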