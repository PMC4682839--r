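test_that("seeds sit one offset along the outward normal, invalid seeds are dropped", {
  s10 <- sphere_surface(10, res = 0.5)
  seeds <- seed_surface(s10, offset = 1)
  r <- sqrt(seeds$x^2 + seeds$y^2 + seeds$z^2)
  expect_lt(max(abs(r - 11)), 0.15)
  expect_true(all(seeds$valid))

  expect_error(seed_surface(s10, offset = 0), "positive")

  # with a field, seeds outside the domain are flagged, not silently kept
  case <- demo_obstacle_case()
  expect_true(any(!case$seeds$valid) || all(case$seeds$valid))
  expect_equal(nrow(case$seeds), nrow(case$surface$vertices))
})

test_that("the thrombus interaction region is 10 percent of the length", {
  s <- tri_surface(rbind(c(0, 0, 0), c(75, 0, 0), c(75, 5, 0), c(0, 0, 5)),
                   rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3)))
  expect_equal(thrombus_interaction_region(s), 7.5)
  s2 <- s; s2$vertices[, 1] <- s2$vertices[, 1] * 100 / 75
  expect_equal(thrombus_interaction_region(s2), 10)
  s0 <- s; s0$vertices[, 1] <- 0
  expect_error(thrombus_interaction_region(s0), "degenerate")
})

test_that("backward tracing is exact in a uniform field and straight in duct flow", {
  # uniform u = c: the backward path is a straight line x(t) = x0 - c t
  cvel <- 0.01  # m/s
  f <- synthetic_field(function(x, y, z) cvel + 0 * x,
                       function(x, y, z) 0, function(x, y, z) 0,
                       nx = 10, L = c(1000, 100, 100))
  p <- trace_backward(f, seed = c(800, 10, 50), atol = 1e-8)
  expect_equal(p$termination, "plane")
  s <- p$samples
  expect_lt(max(abs(s$x - (800 - cvel * 1e6 * s$t))), 1e-6)
  expect_lt(max(abs(s$y - 10)), 1e-9)
  expect_lt(max(abs(s$z - 50)), 1e-9)

  # fully developed duct flow: pathlines keep y and z fixed end to end
  geom <- channel_geometry()
  af <- analytic_flow_field(geom, length_um = 2000, nx = 16, ny = 30, nz = 24)
  seeds <- cbind(900, seq(-600, 600, length.out = 8), seq(20, 180, length.out = 8))
  paths <- trace_pathlines(af, seeds = seeds, atol = 1e-7)
  for (pp in paths) {
    expect_lt(max(abs(pp$samples$y - pp$samples$y[1])), 0.001)
    expect_lt(max(abs(pp$samples$z - pp$samples$z[1])), 0.001)
  }
})

test_that("near-floor adhesion shear matches the analytic wall gradient", {
  geom <- channel_geometry()
  af <- analytic_flow_field(geom, length_um = 2000, nx = 16, ny = 40, nz = 50)
  sh <- compute_shear_field(af)
  p <- trace_pathlines(af, sh, matrix(c(500, 0, 1), 1, 3), atol = 1e-7)[[1]]
  gan <- analytic_duct_shear(geom, 0, 1)
  expect_lt(abs(p$samples$gamma[1] / gan - 1), 0.05)
})

test_that("retrace closure and step-halving keep the spatial error below 0.001 um", {
  case <- demo_obstacle_case()
  sv <- case$seeds[case$seeds$valid, ]
  set.seed(42)
  sel <- sv[sample(nrow(sv), 12), ]
  back <- trace_pathlines(case$field, case$shear, sel, atol = 1e-8)
  sel <- sel[vapply(back, function(p) p$termination == "plane", TRUE), ]
  cl <- retrace_closure(case$field, case$shear, sel, atol = 1e-8)
  expect_lt(max(cl), 0.001)

  # halving the maximum step barely moves the endpoints (tolerance-dominated)
  p1 <- trace_pathlines(case$field, case$shear, sel[1:4, ], atol = 1e-8,
                        h_max = 0.05)
  p2 <- trace_pathlines(case$field, case$shear, sel[1:4, ], atol = 1e-8,
                        h_max = 0.025)
  for (i in 1:4) {
    e1 <- as.numeric(p1[[i]]$samples[nrow(p1[[i]]$samples), c("x", "y", "z")])
    e2 <- as.numeric(p2[[i]]$samples[nrow(p2[[i]]$samples), c("x", "y", "z")])
    expect_lt(sqrt(sum((e1 - e2)^2)), 0.001)
  }
})

test_that("pathline summaries are correct and ordered", {
  mkpath <- function(t, g) structure(list(
    samples = tibble::tibble(t = t, x = t, y = 0, z = 0, gamma = g),
    termination = "plane", direction = "backward", seed = c(0, 0, 0)),
    class = "pathline")

  s <- summarize_pathline(mkpath(seq(0, 5, by = 0.5), rep(5, 11)))
  expect_equal(c(s$gamma_adhesion, s$gamma_peak, s$gamma_mean), c(5, 5, 5))
  expect_equal(s$window_s, 3)

  # samples rising monotonically toward the seed: peak equals adhesion value
  s2 <- summarize_pathline(mkpath(seq(0, 3, by = 0.1), seq(10, 7, by = -0.1)))
  expect_equal(s2$gamma_peak, s2$gamma_adhesion)

  # gamma(t) = t on [0, 3]: trapezoidal time-weighted mean = 1.5
  tt <- seq(0, 3, by = 0.01)
  s3 <- summarize_pathline(mkpath(tt, tt))
  expect_equal(s3$gamma_mean, 1.5, tolerance = 1e-6)

  expect_error(summarize_pathline(mkpath(0, 1)), "at least 2")

  # global ordering invariants on real pathlines
  case <- demo_obstacle_case()
  sv <- case$seeds[case$seeds$valid, ]
  set.seed(7)
  paths <- trace_pathlines(case$field, case$shear, sv[sample(nrow(sv), 15), ],
                           atol = 1e-6)
  sums <- do.call(rbind, lapply(paths, summarize_pathline))
  expect_true(all(sums$gamma_peak >= sums$gamma_adhesion - 1e-9))
  expect_true(all(sums$gamma_peak >= sums$gamma_mean - 1e-9))
  expect_true(all(sums$gamma_adhesion >= 0))
})

test_that("summaries map onto the surface with growth joined by vertex index", {
  s10 <- sphere_surface(10, res = 0.8, t_s = 0)
  nv <- nrow(s10$vertices)
  sums <- tibble::tibble(vertex = seq_len(nv - 5),
                         gamma_adhesion = 100, gamma_peak = 200,
                         gamma_mean = 150)
  s11 <- sphere_surface(11, res = 0.8, t_s = 1)
  gm <- growth_map(s10, s11)
  m <- map_summaries(s10, sums, growth = gm)
  expect_equal(sum(m$table$traced), nv - 5)
  expect_true(all(is.na(m$table$gamma_peak[(nv - 4):nv])))  # flagged, not 0
  expect_equal(unique(m$table$gamma_adhesion[m$table$traced]), 100)
  expect_equal(m$table$growth_um, gm$distance)
  expect_named(m$surface$scalars,
               c("gamma_adhesion", "gamma_peak", "gamma_mean", "growth_um"),
               ignore.order = TRUE)

  bad <- sums; bad$vertex[1] <- nv + 10
  expect_error(map_summaries(s10, bad, growth = gm), "do not match")
})
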