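# Time-correction of z-stacks: same-height contours from consecutive stacks
# are morphed through a signed-distance-field (SDF) level-set evolution whose
# converged intermediates coincide with the zero level sets of linearly
# blended SDFs; an "instantaneous" stack is then resampled at any requested
# timepoint by picking, per z-level, the frame nearest in time.

# exact polygon SDF on a bounding-box-restricted pixel grid.
# Returns list(xs, ys, sdf) with sdf (nx x ny), negative inside material.
# When `polys` is empty, returns NULL (caller handles empty frames).
contour_sdf <- function(polys, xs, ys) {
  .cpp_polygon_sdf(polys, xs, ys)
}

# morph grid covering both contour sets with a margin, aligned to the pixel
# lattice of the acquisition (pixel centres at multiples of pixel_um offset
# is irrelevant for sub-pixel contouring)
morph_grid <- function(contours1, contours2, pixel_um, margin_px = 6) {
  pts <- do.call(rbind, lapply(c(contours1, contours2),
                               function(e) if (is.list(e)) e$polygon else e))
  if (is.null(pts)) return(NULL)
  m <- margin_px * pixel_um
  xr <- range(pts[, 1]) + c(-m, m)
  yr <- range(pts[, 2]) + c(-m, m)
  list(xs = seq(xr[1], xr[2], by = pixel_um),
       ys = seq(yr[1], yr[2], by = pixel_um))
}

# restriction of the image pixel lattice to the contours' bounding box
pixel_aligned_grid <- function(polys, width_px, height_px, pixel_um,
                               margin_px = 6) {
  pts <- do.call(rbind, polys)
  if (is.null(pts) || !nrow(pts)) return(NULL)
  xs_full <- px_coords(width_px, pixel_um)
  ys_full <- px_coords(height_px, pixel_um)
  m <- margin_px * pixel_um
  ix <- which(xs_full >= min(pts[, 1]) - m & xs_full <= max(pts[, 1]) + m)
  iy <- which(ys_full >= min(pts[, 2]) - m & ys_full <= max(pts[, 2]) + m)
  if (!length(ix) || !length(iy)) return(NULL)
  list(xs = xs_full[ix], ys = ys_full[iy], ix = ix, iy = iy)
}

# SDF for an empty frame: uniform positive distance from a collapse point
# (the other frame's area centroid), so growth from / shrinkage to nothing
# realises as inflation / deflation about that point
empty_sdf <- function(collapse, xs, ys) {
  outer(xs, ys, function(px, py) sqrt((px - collapse[1])^2 + (py - collapse[2])^2))
}

sdf_pair <- function(contours1, contours2, pixel_um, grid = NULL) {
  p1 <- lapply(contours1, function(e) if (is.list(e)) e$polygon else e)
  p2 <- lapply(contours2, function(e) if (is.list(e)) e$polygon else e)
  if (!length(p1) && !length(p2)) return(NULL)
  if (is.null(grid)) grid <- morph_grid(p1, p2, pixel_um)
  collapse <- if (!length(p1)) {
    areas <- vapply(p2, function(p) abs(polygon_area(p)), numeric(1))
    polygon_centroid(p2[[which.max(areas)]])
  } else if (!length(p2)) {
    areas <- vapply(p1, function(p) abs(polygon_area(p)), numeric(1))
    polygon_centroid(p1[[which.max(areas)]])
  } else NULL
  s1 <- if (length(p1)) contour_sdf(p1, grid$xs, grid$ys) else empty_sdf(collapse, grid$xs, grid$ys)
  s2 <- if (length(p2)) contour_sdf(p2, grid$xs, grid$ys) else empty_sdf(collapse, grid$xs, grid$ys)
  list(grid = grid, s1 = s1, s2 = s2)
}

# zero-level contours of a blended SDF at parameter s in [0, 1]
blend_contours <- function(pair, s) {
  sdf <- (1 - s) * pair$s1 + s * pair$s2
  if (all(sdf >= 0)) return(list())
  cl <- contourLines(x = pair$grid$xs, y = pair$grid$ys, z = sdf, levels = 0)
  out <- list()
  for (cc in cl) {
    poly <- cbind(cc$x, cc$y)
    if (nrow(poly) > 1 && all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-12))
      poly <- poly[-nrow(poly), , drop = FALSE]
    if (nrow(poly) >= 3) out[[length(out) + 1L]] <- poly
  }
  out
}

check_simple_polygons <- function(contours, where = "morph_pair") {
  for (e in contours) {
    p <- if (is.list(e)) e$polygon else e
    if (!is.matrix(p) || nrow(p) < 3)
      stopf("%s: each contour must be a polygon matrix with >= 3 vertices", where)
    if (anyNA(p)) stopf("%s: polygon contains NA", where)
    if (abs(polygon_area(p)) < 1e-12)
      stopf("%s: degenerate (zero-area / self-intersecting) polygon", where)
  }
  invisible(TRUE)
}

#' Morph between two same-height contour sets
#'
#' Generates `n_intermediates` contour sets transitioning from the shape at
#' timepoint 1 to the shape at timepoint 2. The morph is a level-set
#' evolution of the signed-distance field initialised at the first shape and
#' driven toward the second; its converged intermediates are the zero level
#' sets of linearly blended signed-distance fields, which is what is
#' computed (symmetric, topology-robust, and testable against a dense
#' analytic oracle). Empty frames are represented as a uniform positive
#' distance from a collapse point so appearance/disappearance realises as
#' inflation/deflation.
#'
#' @param contours1,contours2 lists of closed polygons (n x 2 matrices, um)
#'   or contour entries from [extract_contours()]; either may be empty.
#' @param n_intermediates number of intermediate frames.
#' @param pixel_um grid step (um) of the signed-distance grid (the slice
#'   pixel grid).
#' @param grid optional list(xs, ys) overriding the automatic grid.
#' @return list with `s` (morph parameters k/(n+1)) and `contours` (list of
#'   contour-polygon lists, one per intermediate).
#' @export
morph_pair <- function(contours1, contours2, n_intermediates, pixel_um,
                       grid = NULL) {
  check_simple_polygons(contours1)
  check_simple_polygons(contours2)
  pair <- sdf_pair(contours1, contours2, pixel_um, grid)
  svals <- seq_len(n_intermediates) / (n_intermediates + 1)
  if (is.null(pair))
    return(list(s = svals, contours = rep(list(list()), n_intermediates)))
  list(s = svals,
       contours = lapply(svals, function(s) blend_contours(pair, s)))
}

#' Timestamps of morphed intermediate frames
#'
#' Intermediate k of n between acquired times ta < tb is stamped
#' ta + k (tb - ta) / (n + 1): linear in the morph parameter. Acquired
#' frames keep their metadata times exactly.
#'
#' @param ta,tb bracketing acquired timestamps (s), `ta < tb`.
#' @param n number of intermediates.
#' @return numeric vector of n timestamps.
#' @export
intermediate_times <- function(ta, tb, n) {
  if (!(tb > ta)) stopf("acquired timestamps must be strictly increasing")
  ta + seq_len(n) * (tb - ta) / (n + 1)
}

#' Build a per-z contour timeline from consecutive z-stacks
#'
#' Segments every stack, extracts per-slice contours, groups them by z-level
#' (matched within half a slice thickness) and plans morphed intermediate
#' frames between consecutive stacks so the frame-time increment is at most
#' `increment_s`.
#'
#' @param stacks list of `zstack` objects, in acquisition order.
#' @param threshold segmentation threshold ("auto" = stack-wide Otsu of the
#'   first stack, reused for all stacks for consistency).
#' @param increment_s maximum intermediate sampling increment (s).
#' @param min_area_um2 see [segment_slice()].
#' @return a `contour_timeline`.
#' @export
contour_timeline <- function(stacks, threshold = "auto", increment_s = 0.06,
                             min_area_um2 = pi * 1^2) {
  stopifnot(length(stacks) >= 2)
  if (identical(threshold, "auto")) threshold <- otsu_threshold(stacks[[1]])
  segs <- lapply(stacks, segment_stack, threshold = threshold,
                 min_area_um2 = min_area_um2)
  z_ref <- segs[[1]]$z_um
  dz <- if (length(z_ref) > 1) diff(z_ref[1:2]) else 1
  for (s in segs[-1]) {
    if (length(s$z_um) != length(z_ref) || any(abs(s$z_um - z_ref) > dz / 2))
      stopf("stacks do not share z-levels within half a slice thickness")
    if (any(diff(vapply(segs, function(x) x$t_s[1], numeric(1))) <= 0))
      stopf("stack acquisition times are not monotone")
  }
  levels <- vector("list", length(z_ref))
  for (k in seq_along(z_ref)) {
    frames <- lapply(segs, function(s) list(
      t = s$t_s[k],
      contours = extract_contours(s$masks[[k]], s$pixel_um, z = s$z_um[k],
                                  t = s$t_s[k]),
      mask = s$masks[[k]]))
    tacq <- vapply(frames, `[[`, numeric(1), "t")
    if (is.unsorted(tacq, strictly = TRUE))
      stopf("non-monotone acquisition timestamps at z = %.2f um", z_ref[k])
    n_int <- pmax(0, ceiling(diff(tacq) / increment_s) - 1)
    levels[[k]] <- list(z = z_ref[k], frames = frames, n_intermediates = n_int)
  }
  structure(list(levels = levels, z_um = z_ref,
                 pixel_um = segs[[1]]$pixel_um,
                 width_px = segs[[1]]$width_px,
                 height_px = segs[[1]]$height_px,
                 threshold = threshold,
                 increment_s = increment_s,
                 acq_window = c(end_first = max(stacks[[1]]$t_s),
                                start_last = min(stacks[[length(stacks)]]$t_s))),
            class = "contour_timeline")
}

#' All frame times (acquired + intermediates) at one z-level
#'
#' @param timeline a [contour_timeline()].
#' @param z_index z-level index.
#' @return numeric vector of frame timestamps, strictly increasing.
#' @export
frame_times <- function(timeline, z_index) {
  lv <- timeline$levels[[z_index]]
  tacq <- vapply(lv$frames, `[[`, numeric(1), "t")
  out <- tacq[1]
  for (m in seq_len(length(tacq) - 1)) {
    n <- lv$n_intermediates[m]
    if (n > 0) out <- c(out, intermediate_times(tacq[m], tacq[m + 1], n))
    out <- c(out, tacq[m + 1])
  }
  out
}

#' Resample an instantaneous z-stack at a single timepoint
#'
#' For each z-level, selects the acquired or morphed frame whose timestamp is
#' nearest the requested timepoint. The realised time band
#' `delta_t_span` = max - min of the selected frame times is reported; by
#' nearest-frame selection it is bounded by twice the intermediate sampling
#' increment.
#'
#' @param timeline a [contour_timeline()].
#' @param t_star requested timepoint (s); must lie after the end of the first
#'   stack's acquisition and before the start of the last stack's.
#' @return an `instantaneous_stack`: per-z masks and contours, selected frame
#'   times, `delta_t_span`, `t_star`.
#' @export
sample_instantaneous <- function(timeline, t_star) {
  w <- timeline$acq_window
  if (t_star <= w["end_first"] || t_star >= w["start_last"])
    stopf(paste0("t* = %.3f s is outside the correctable window ",
                 "(%.3f, %.3f) s: timepoints before the end of the first ",
                 "stack or after the start of the last cannot be corrected"),
          t_star, w["end_first"], w["start_last"])
  nz <- length(timeline$levels)
  masks <- vector("list", nz)
  contours <- vector("list", nz)
  t_sel <- numeric(nz)
  s_sel <- numeric(nz)
  for (k in seq_len(nz)) {
    lv <- timeline$levels[[k]]
    tacq <- vapply(lv$frames, `[[`, numeric(1), "t")
    m <- findInterval(t_star, tacq, rightmost.closed = TRUE)
    m <- min(max(m, 1), length(tacq) - 1)
    n <- lv$n_intermediates[m]
    delta <- (tacq[m + 1] - tacq[m]) / (n + 1)
    j <- round((t_star - tacq[m]) / delta)
    j <- min(max(j, 0), n + 1)
    t_sel[k] <- tacq[m] + j * delta
    s_sel[k] <- j / (n + 1)
    if (j == 0 || j == n + 1) {
      fr <- lv$frames[[m + (j > 0)]]
      masks[[k]] <- fr$mask
      contours[[k]] <- lapply(fr$contours, `[[`, "polygon")
    } else {
      # the SDF grid is aligned to the image pixel lattice so the blended
      # mask is read directly off the field's sign at pixel centres
      grid <- pixel_aligned_grid(c(lapply(lv$frames[[m]]$contours, `[[`, "polygon"),
                                   lapply(lv$frames[[m + 1]]$contours, `[[`, "polygon")),
                                 timeline$width_px, timeline$height_px,
                                 timeline$pixel_um)
      pair <- if (is.null(grid)) NULL else
        sdf_pair(lv$frames[[m]]$contours, lv$frames[[m + 1]]$contours,
                 timeline$pixel_um, grid = grid)
      masks[[k]] <- matrix(FALSE, timeline$height_px, timeline$width_px)
      contours[[k]] <- list()
      if (!is.null(pair)) {
        s <- j / (n + 1)
        contours[[k]] <- blend_contours(pair, s)
        sdfb <- (1 - s) * pair$s1 + s * pair$s2
        masks[[k]][grid$iy, grid$ix] <- t(sdfb < 0)
      }
    }
  }
  structure(list(z_um = timeline$z_um, masks = masks, contours = contours,
                 t_selected = t_sel, morph_parameter = s_sel,
                 delta_t_span = max(t_sel) - min(t_sel),
                 t_star = t_star, pixel_um = timeline$pixel_um,
                 width_px = timeline$width_px, height_px = timeline$height_px),
            class = "instantaneous_stack")
}

#' @export
print.instantaneous_stack <- function(x, ...) {
  cat(sprintf("<instantaneous_stack> t* = %.3f s, %d z-levels, dT span = %.1f ms\n",
              x$t_star, length(x$z_um), 1000 * x$delta_t_span))
  invisible(x)
}

#' Time-corrected surface at a requested timepoint
#'
#' Composes [contour_timeline()], [sample_instantaneous()] and
#' [build_surface()] (with ripple filtering) to reconstruct the instantaneous
#' thrombus surface at `t_star`.
#'
#' @param stacks list of `zstack` objects (or a ready `contour_timeline`).
#' @param t_star requested timepoint (s).
#' @param threshold,increment_s passed to [contour_timeline()].
#' @param smooth,... passed to [build_surface()].
#' @return a [tri_surface] tagged with provenance `t_s = t_star` and
#'   attribute `delta_t_span`.
#' @export
time_corrected_surface <- function(stacks, t_star, threshold = "auto",
                                   increment_s = 0.06, smooth = TRUE, ...) {
  timeline <- if (inherits(stacks, "contour_timeline")) stacks
              else contour_timeline(stacks, threshold = threshold,
                                    increment_s = increment_s)
  inst <- sample_instantaneous(timeline, t_star)
  seg <- structure(list(masks = inst$masks, z_um = inst$z_um,
                        t_s = inst$t_selected, pixel_um = inst$pixel_um,
                        threshold = timeline$threshold, stack_index = NA_integer_,
                        width_px = inst$width_px, height_px = inst$height_px),
                   class = "segmented_stack")
  surf <- build_surface(seg, smooth = smooth, t_s = t_star, ...)
  attr(surf, "delta_t_span") <- inst$delta_t_span
  surf
}
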