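test_that("8-bit conversion uses the fixed linear scale with round-half-up", {
  expect_identical(convert_to_8bit(matrix(4095L))[1, 1], 255L)
  expect_identical(convert_to_8bit(matrix(0L))[1, 1], 0L)
  expect_identical(convert_to_8bit(matrix(2048L))[1, 1], 128L)  # 127.53 -> 128
  expect_error(convert_to_8bit(matrix(1), bit_depth = 4), "at least 8")
})

test_that("segmentation thresholds and speck removal behave as specified", {
  px <- 0.5
  xc <- (1:80 - 40.5) * px
  G <- expand.grid(y = xc, x = xc)
  disk <- matrix(ifelse(G$x^2 + G$y^2 <= 100, 200L, 0L), 80, 80)

  expect_warning(m0 <- segment_slice(matrix(0L, 10, 10), "auto", px),
                 "blank")
  expect_false(any(m0))

  m <- segment_slice(disk, 100, px)
  expect_equal(max(EBImage::bwlabel(m * 1L)), 1)
  expect_lt(abs(sum(m) * px^2 / (pi * 100) - 1), 0.02)

  expect_true(all(segment_slice(disk, 0, px, min_area_um2 = 0)))

  # a 1-pixel speck is removed at the platelet-scale minimum area
  speck <- disk
  speck[3, 3] <- 200L
  ms <- segment_slice(speck, 100, px)
  expect_equal(max(EBImage::bwlabel(ms * 1L)), 1)
})

test_that("contour extraction yields labelled closed polygons with matching area", {
  px <- 0.5
  xc <- (1:80 - 40.5) * px
  G <- expand.grid(y = xc, x = xc)
  expect_length(extract_contours(matrix(FALSE, 10, 10), px), 0)

  disk <- matrix(G$x^2 + G$y^2 <= 100, 80, 80)
  cs <- extract_contours(disk, px)
  expect_length(cs, 1)
  a_poly <- abs(thromboflow:::polygon_area(cs[[1]]$polygon))
  expect_lt(abs(a_poly / (sum(disk) * px^2) - 1), 0.02)
  expect_gt(thromboflow:::polygon_area(cs[[1]]$polygon), 0)  # CCW material

  two <- matrix(pmin((G$x - 8)^2 + G$y^2, (G$x + 8)^2 + G$y^2) <= 16, 80, 80)
  cs2 <- extract_contours(two, px)
  expect_length(cs2, 2)
  expect_setequal(vapply(cs2, `[[`, numeric(1), "label"), c(1, 2))
})

test_that("surface reconstruction recovers analytic volumes and planar faces", {
  hs <- hemisphere_stack(r = 15)
  surf <- build_surface(hs$stack)
  expect_true(is_watertight(surf)$watertight)
  expect_lt(abs(mesh_volume(surf) / (2 / 3 * pi * 15^3) - 1), 0.02)

  tr <- trapezoid_stack()
  ts <- build_surface(tr)
  v_exact <- 0.5 * (30 + 15) * 20 * 30
  expect_lt(abs(mesh_volume(ts) / v_exact - 1), 0.02)
  # slanted face planarity after ripple filtering: <= 1 slice thickness
  v <- ts$vertices
  sel <- v[, 3] > 2 & v[, 3] < 18 & v[, 1] > 3 & abs(v[, 2]) < 12
  dev <- abs(v[sel, 1] + 0.75 * v[sel, 3] - 15) / sqrt(1 + 0.75^2)
  expect_lt(max(dev), 0.5)

  one <- tr
  one$masks <- c(tr$masks[2], lapply(tr$masks[-2], function(m) m & FALSE))
  expect_error(build_surface(one), "at least 2 slices")
})

test_that("halving the slice thickness does not increase the volume error", {
  err <- vapply(c(1.0, 0.5), function(dz) {
    hs <- hemisphere_stack(r = 15, slice_um = dz)
    abs(mesh_volume(build_surface(hs$stack, smooth = FALSE)) /
          (2 / 3 * pi * 15^3) - 1)
  }, numeric(1))
  expect_lte(err[2], err[1])
})

test_that("ripple filter attenuates inter-slice oscillation, preserving volume", {
  seg <- cylinder_stack()
  raw <- build_surface(seg, smooth = FALSE, floor_z = NULL)
  flt <- ripple_filter(seg, floor_z = NULL)
  barrel <- function(s) {
    v <- s$vertices
    sel <- v[, 3] > 5 & v[, 3] < 15
    sqrt(v[sel, 1]^2 + v[sel, 2]^2)
  }
  expect_gt(sd(barrel(raw)) / sd(barrel(flt)), 5)            # >= 5x reduction
  expect_lt(abs(mean(barrel(flt)) / mean(barrel(raw)) - 1), 0.01)
  expect_lt(abs(mesh_volume(flt) / mesh_volume(raw) - 1), 0.01)
  expect_true(is_watertight(flt)$watertight)
})

test_that("ripple filter passes an analytically smooth hemisphere nearly unchanged", {
  hs <- phantom_surface(make_semi_ellipsoid_phantom(15, 15, 15), 0,
                        resolution = 0.5)
  hf <- ripple_filter(hs)
  dome <- hs$vertices[, 3] > 1
  expect_lt(max(abs(sqrt(rowSums(hf$vertices[dome, ]^2)) - 15)), 0.25)
  expect_lt(abs(mesh_volume(hf) / mesh_volume(hs) - 1), 0.01)
})

test_that("surface metrics report volume and flow-aligned bounding box", {
  # unit cube, outward orientation
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  F <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7),  # z faces
             c(1,2,5), c(2,6,5), c(3,7,4), c(4,7,8),  # y faces
             c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))  # x faces
  cube <- tri_surface(V, F)
  m <- surface_metrics(cube)
  expect_equal(m$volume_um3, 1)
  expect_equal(c(m$length_um, m$width_um, m$height_um), c(1, 1, 1))

  hemi <- phantom_surface(make_semi_ellipsoid_phantom(15, 15, 15), 0,
                          resolution = 0.5)
  mh <- surface_metrics(hemi)
  expect_lt(abs(mh$volume_um3 / (2 / 3 * pi * 15^3) - 1), 0.01)
  expect_lt(abs(mh$height_um - 15), 0.3)

  open_mesh <- tri_surface(V, F[-1, ])
  expect_error(surface_metrics(open_mesh), "boundary edge")
})
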