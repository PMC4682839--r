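# Backward pathline tracing and shear-history summaries.

# padded interpolation arrays: wall layers carry zero velocity (no-slip) so
# trilinear interpolation tapers to zero at the physical boundaries; the
# inlet layer carries the inlet profile; the outlet replicates the last
# plane; the shear field is edge-replicated (shear is largest AT walls).
interp_arrays <- function(field, shear) {
  g <- field$grid
  nx <- length(g$xc); ny <- length(g$yc); nz <- length(g$zc)
  xs <- c(g$xf[1], g$xc, g$xf[nx + 1])
  ys <- c(g$yf[1], g$yc, g$yf[ny + 1])
  zs <- c(g$zf[1], g$zc, g$zf[nz + 1])
  pad <- function(A, xlo, xhi, wall0 = TRUE) {
    P <- array(0, dim = c(nx + 2, ny + 2, nz + 2))
    P[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- A
    P[1, 2:(ny + 1), 2:(nz + 1)] <- xlo
    P[nx + 2, 2:(ny + 1), 2:(nz + 1)] <- xhi
    if (!wall0) {
      P[, 1, ] <- P[, 2, ]; P[, ny + 2, ] <- P[, ny + 1, ]
      P[, , 1] <- P[, , 2]; P[, , nz + 2] <- P[, , nz + 1]
      P[1, , ] <- P[2, , ]; P[nx + 2, , ] <- P[nx + 1, , ]
    }
    P
  }
  um_s <- 1e6  # m/s -> um/s
  list(xs = xs, ys = ys, zs = zs,
       u = pad(field$uc, field$uin, field$uc[nx, , ]) * um_s,
       v = pad(field$vc, 0, field$vc[nx, , ]) * um_s,
       w = pad(field$wc, 0, field$wc[nx, , ]) * um_s,
       g = pad(shear$gamma, 0, 0, wall0 = FALSE))
}

#' Seed points above a thrombus surface
#'
#' One seed per surface vertex, offset along the outward vertex normal
#' (default 1 um, half a platelet diameter, clearing the no-slip surface).
#' Seeds falling inside the obstacle or outside the fluid domain are dropped
#' and flagged.
#'
#' @param surface a watertight, outward-oriented [tri_surface].
#' @param field optional `flow_field` used to validate seeds.
#' @param offset normal offset (um); must be positive.
#' @return tibble with vertex index, seed coordinates and validity flag.
#' @export
seed_surface <- function(surface, field = NULL, offset = 1.0) {
  if (offset <= 0)
    stopf("offset must be positive: seeds on the no-slip surface carry zero velocity")
  wt <- .cpp_edge_audit(surface$faces)
  if (!isTRUE(wt$watertight)) stopf("surface must be watertight")
  N <- vertex_normals(surface)
  seeds <- surface$vertices + offset * N
  valid <- rep(TRUE, nrow(seeds))
  if (!is.null(field)) {
    g <- field$grid
    valid <- seeds[, 1] > g$xf[1] & seeds[, 1] < g$xf[length(g$xf)] &
      seeds[, 2] > g$yf[1] & seeds[, 2] < g$yf[length(g$yf)] &
      seeds[, 3] > g$zf[1] & seeds[, 3] < g$zf[length(g$zf)]
    inside_obs <- rep(FALSE, nrow(seeds))
    if (!is.null(field$obstacle) && any(valid))
      inside_obs[valid] <- .cpp_points_in_mesh(seeds[valid, , drop = FALSE],
                                               field$obstacle$vertices,
                                               field$obstacle$faces)
    valid <- valid & !inside_obs
  }
  if (!any(valid)) stopf("all seed points are invalid")
  tibble::tibble(vertex = seq_len(nrow(seeds)),
                 x = seeds[, 1], y = seeds[, 2], z = seeds[, 3],
                 valid = valid)
}

#' Thrombus interaction region extent
#'
#' The upstream region where approaching platelets feel thrombus-induced
#' shear gradients: 10 percent of the thrombus length, measured upstream
#' from its most-upstream point.
#'
#' @param surface a [tri_surface].
#' @param flow_direction axis of flow ("x").
#' @param fraction TIR fraction of the length.
#' @return extent (um).
#' @export
thrombus_interaction_region <- function(surface, flow_direction = "x",
                                        fraction = 0.10) {
  ax <- match(flow_direction, c("x", "y", "z"))
  if (is.na(ax)) stopf("flow_direction must be x, y or z")
  L <- diff(range(surface$vertices[, ax]))
  if (L <= 0) stopf("degenerate geometry: zero length along the flow direction")
  fraction * L
}

termination_labels <- c("plane", "stagnation", "time_cap", "exited",
                        "time_end", "max_steps")

#' Trace pathlines through a solved flow field
#'
#' Integrates dX/dt = -U(X) (backward, toward the inlet) or +U(X) (forward)
#' with an embedded adaptive Dormand-Prince Runge-Kutta 4(5) scheme and
#' trilinear velocity interpolation; the local shear rate is sampled at every
#' accepted step. Integration stops at the stop planes (default: the domain
#' inlet/outlet), on stagnation, at the time cap, or after `t_end` seconds
#' when given.
#'
#' @param field a `flow_field`.
#' @param shear matching `shear_field` (computed if `NULL`).
#' @param seeds matrix/data frame of seed coordinates (um), e.g. from
#'   [seed_surface()] (only valid seeds are traced).
#' @param direction "backward" or "forward" in time.
#' @param atol absolute per-step spatial error tolerance (um); the default
#'   keeps the accumulated spatial error along a pathline below 0.001 um
#'   (verified by backward/forward retrace closure).
#' @param h_max maximum step (s).
#' @param t_cap time cap (s) for recirculating seeds that never reach the
#'   inlet.
#' @param eps_stag stagnation speed (m/s).
#' @param stop_x stop planes (um), default the domain x-extents.
#' @param t_end integrate for exactly this elapsed time (s), ignoring stop
#'   planes (used for retracing); `NULL` to disable.
#' @param max_steps safety cap on accepted steps.
#' @return list of `pathline` objects: `samples` tibble (elapsed t (s),
#'   x, y, z (um), gamma (1/s)) and `termination` reason.
#' @export
trace_pathlines <- function(field, shear = NULL, seeds, direction = "backward",
                            atol = 1e-8, h_max = 0.05, t_cap = 30,
                            eps_stag = 1e-9, stop_x = NULL, t_end = NULL,
                            max_steps = 500000L) {
  if (is.null(shear)) shear <- compute_shear_field(field)
  if (is.data.frame(seeds)) {
    if ("valid" %in% names(seeds)) seeds <- seeds[seeds$valid, , drop = FALSE]
    seeds <- as.matrix(seeds[, c("x", "y", "z")])
  }
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  ia <- interp_arrays(field, shear)
  if (is.null(stop_x))
    stop_x <- c(field$grid$xf[1], field$grid$xf[length(field$grid$xf)])
  dir <- if (identical(direction, "backward")) -1 else 1
  raw <- .cpp_trace(ia$xs, ia$ys, ia$zs, ia$u, ia$v, ia$w, ia$g,
                    seeds, dir, atol, h_max, t_cap,
                    eps_stag * 1e6,  # m/s -> um/s
                    stop_x[1], stop_x[2],
                    if (is.null(t_end)) -1 else t_end,
                    as.integer(max_steps))
  lapply(seq_along(raw), function(i) {
    m <- raw[[i]]$samples
    structure(list(
      samples = tibble::tibble(t = m[, 1], x = m[, 2], y = m[, 3],
                               z = m[, 4], gamma = m[, 5]),
      termination = termination_labels[raw[[i]]$reason],
      direction = direction,
      seed = seeds[i, ]), class = "pathline")
  })
}

#' @rdname trace_pathlines
#' @param seed a single seed coordinate (length-3 vector).
#' @param ... passed to [trace_pathlines()].
#' @export
trace_backward <- function(field, shear = NULL, seed, ...) {
  trace_pathlines(field, shear, matrix(seed, 1, 3), direction = "backward",
                  ...)[[1]]
}

#' @export
print.pathline <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<pathline> %s, %d samples over %.4f s, terminated: %s\n",
              x$direction, n, max(x$samples$t), x$termination))
  invisible(x)
}

#' Backward/forward retrace closure error
#'
#' Integrates each seed backward for its full pathline, then forward from the
#' endpoint for the same elapsed time; returns the distance between the
#' return point and the seed. This measures the accumulated spatial error of
#' the integration.
#'
#' @param field a `flow_field`.
#' @param shear matching `shear_field` (computed if `NULL`).
#' @param seeds seed coordinates (matrix or [seed_surface()] tibble).
#' @param ... passed to [trace_pathlines()].
#' @return numeric vector of closure distances (um), one per seed.
#' @export
retrace_closure <- function(field, shear = NULL, seeds, ...) {
  if (is.null(shear)) shear <- compute_shear_field(field)
  back <- trace_pathlines(field, shear, seeds, direction = "backward", ...)
  vapply(back, function(p) {
    n <- nrow(p$samples)
    if (n < 2) return(0)
    endp <- as.numeric(p$samples[n, c("x", "y", "z")])
    tb <- p$samples$t[n]
    fwd <- trace_pathlines(field, shear, matrix(endp, 1, 3),
                           direction = "forward", t_end = tb,
                           stop_x = c(-Inf, Inf), ...)[[1]]
    m <- nrow(fwd$samples)
    ret <- as.numeric(fwd$samples[m, c("x", "y", "z")])
    sqrt(sum((ret - p$seed)^2))
  }, numeric(1))
}

#' Shear-rate history summary of one pathline
#'
#' Summarises the shear a platelet experienced over the last `window`
#' seconds prior to (potential) adhesion: the value at the seed
#' (gamma_adhesion), the maximum over the window (gamma_peak) and the
#' time-weighted (trapezoidal) mean (gamma_mean). The window is truncated
#' for shorter pathlines.
#'
#' @param path a `pathline` (samples ordered from the seed outward).
#' @param window summary window (s).
#' @return one-row tibble: gamma_adhesion, gamma_peak, gamma_mean (1/s),
#'   realised window (s), sample count, termination reason.
#' @export
summarize_pathline <- function(path, window = 3.0) {
  s <- path$samples
  if (is.null(s) || nrow(s) == 0) stopf("empty pathline")
  if (nrow(s) < 2) stopf("pathline must contain at least 2 samples")
  keep <- s$t <= window + 1e-12
  sw <- s[keep, , drop = FALSE]
  tt <- sw$t; gg <- sw$gamma
  dur <- max(tt) - min(tt)
  gmean <- if (dur > 0) {
    sum(diff(tt) * (head(gg, -1) + tail(gg, -1)) / 2) / dur
  } else mean(gg)
  tibble::tibble(gamma_adhesion = gg[1],
                 gamma_peak = max(gg),
                 gamma_mean = gmean,
                 window_s = dur,
                 n_samples = nrow(sw),
                 termination = path$termination)
}

#' Map pathline summaries onto the thrombus surface
#'
#' Populates per-vertex scalar channels gamma_adhesion, gamma_peak and
#' gamma_mean (and growth, when a [growth_map()] on the same surface is
#' given); vertices whose seeds were dropped are `NA` and flagged, never
#' zero-filled.
#'
#' @param surface the seeded [tri_surface].
#' @param summaries tibble with a `vertex` column and the three gamma
#'   columns (one row per traced seed), e.g. built from
#'   [summarize_pathline()] results.
#' @param growth optional [growth_map()] whose reference surface matches
#'   `surface`.
#' @return a `surface_shear_map`: the surface with scalar channels plus a
#'   per-vertex tibble.
#' @export
map_summaries <- function(surface, summaries, growth = NULL) {
  nv <- nrow(surface$vertices)
  if (!all(c("vertex", "gamma_adhesion", "gamma_peak", "gamma_mean") %in%
           names(summaries)))
    stopf("summaries must have columns vertex, gamma_adhesion, gamma_peak, gamma_mean")
  if (any(summaries$vertex < 1 | summaries$vertex > nv))
    stopf("summary vertex indices do not match the surface")
  chan <- function(col) {
    v <- rep(NA_real_, nv)
    v[summaries$vertex] <- summaries[[col]]
    v
  }
  surf <- surface
  surf$scalars$gamma_adhesion <- chan("gamma_adhesion")
  surf$scalars$gamma_peak <- chan("gamma_peak")
  surf$scalars$gamma_mean <- chan("gamma_mean")
  if (!is.null(growth)) {
    if (length(growth$distance) != nv)
      stopf("growth map does not match the surface vertex count")
    surf$scalars$growth_um <- growth$distance
  }
  tab <- tibble::tibble(vertex = seq_len(nv),
                        x = surface$vertices[, 1],
                        y = surface$vertices[, 2],
                        z = surface$vertices[, 3],
                        gamma_adhesion = surf$scalars$gamma_adhesion,
                        gamma_peak = surf$scalars$gamma_peak,
                        gamma_mean = surf$scalars$gamma_mean,
                        growth_um = if (!is.null(growth)) growth$distance else NA_real_,
                        traced = !is.na(surf$scalars$gamma_adhesion))
  structure(list(surface = surf, table = tab), class = "surface_shear_map")
}

#' @export
print.surface_shear_map <- function(x, ...) {
  cat(sprintf("<surface_shear_map> %d vertices, %d traced\n",
              nrow(x$table), sum(x$table$traced)))
  invisible(x)
}
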