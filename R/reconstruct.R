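#' Convert native-bit-depth images to 8 bit
#'
#' Fixed linear rescale value * 255 / (2^bit_depth - 1), rounded half-up,
#' applied before thresholding (deterministic across platforms).
#'
#' @param x an intensity matrix or a `zstack`.
#' @param bit_depth native bit depth (taken from the stack when `x` is a
#'   `zstack`).
#' @return same shape as `x`, 8-bit intensities.
#' @export
convert_to_8bit <- function(x, bit_depth = 12) {
  if (inherits(x, "zstack")) {
    if (x$bit_depth == 8) return(x)
    x$slices <- lapply(x$slices, convert_to_8bit, bit_depth = x$bit_depth)
    x$bit_depth <- 8L
    return(x)
  }
  if (bit_depth < 8) stopf("bit depth must be at least 8")
  out <- floor(x * 255 / (2^bit_depth - 1) + 0.5)   # round half-up
  storage.mode(out) <- "integer"
  out
}

#' Otsu threshold over a whole stack
#'
#' The threshold is computed once from the pooled 8-bit histogram of all
#' slices, so segmentation is consistent along z.
#'
#' @param stack a `zstack` (converted to 8 bit if needed).
#' @return threshold intensity on the 0..255 scale.
#' @export
otsu_threshold <- function(stack) {
  stack <- convert_to_8bit(stack)
  pix <- unlist(stack$slices, use.names = FALSE)
  if (max(pix) == min(pix)) {
    warning("blank stack: auto threshold undefined, returning Inf (empty masks)")
    return(Inf)
  }
  thr <- EBImage::otsu(matrix(pix / 255, ncol = 1), range = c(0, 1), levels = 256)
  thr * 255
}

#' Threshold one slice into a binary mask
#'
#' Pixels at or above the threshold are foreground; connected components
#' smaller than `min_area_um2` (default: the area of a 2-um-diameter disk,
#' the platelet scale) are removed as segmentation specks.
#'
#' @param image 8-bit intensity matrix.
#' @param threshold intensity threshold, or "auto" for Otsu on this slice
#'   (prefer [otsu_threshold()] on the stack).
#' @param pixel_um pixel size (um/pixel).
#' @param min_area_um2 minimum component area (um^2).
#' @return logical mask matrix.
#' @export
segment_slice <- function(image, threshold, pixel_um,
                          min_area_um2 = pi * 1^2) {
  if (identical(threshold, "auto")) {
    if (max(image) == min(image)) {
      warning("blank image with 'auto' threshold: returning empty mask")
      return(matrix(FALSE, nrow(image), ncol(image)))
    }
    threshold <- EBImage::otsu(matrix(image / 255, ncol = 1),
                               range = c(0, 1), levels = 256) * 255
  }
  mask <- image >= threshold
  if (any(mask) && min_area_um2 > 0) {
    min_px <- min_area_um2 / pixel_um^2
    lab <- EBImage::bwlabel(mask * 1L)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_px)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

#' Segment a full z-stack
#'
#' @param stack a `zstack`.
#' @param threshold "auto" (stack-wide Otsu) or a numeric 8-bit intensity.
#' @param min_area_um2 see [segment_slice()].
#' @return a `segmented_stack`: binary masks plus per-slice z/t metadata.
#' @export
segment_stack <- function(stack, threshold = "auto", min_area_um2 = pi * 1^2) {
  stack8 <- convert_to_8bit(stack)
  thr <- if (identical(threshold, "auto")) otsu_threshold(stack8) else threshold
  masks <- lapply(stack8$slices, segment_slice, threshold = thr,
                  pixel_um = stack8$pixel_um, min_area_um2 = min_area_um2)
  structure(list(masks = masks, z_um = stack8$z_um, t_s = stack8$t_s,
                 pixel_um = stack8$pixel_um, threshold = thr,
                 stack_index = stack8$stack_index,
                 width_px = ncol(masks[[1]]), height_px = nrow(masks[[1]])),
            class = "segmented_stack")
}

#' Extract closed sub-pixel contours from a binary mask
#'
#' One closed polygon per connected component (plus one per hole), traced as
#' the 0.5 iso-level of the mask with sub-pixel linear interpolation, scaled
#' to um. Material contours are wound counter-clockwise, holes clockwise.
#' Components touching the image border are closed along the border and
#' flagged.
#'
#' @param mask logical matrix (rows = y, columns = x).
#' @param pixel_um pixel size (um/pixel).
#' @param z,t slice position (um) and timestamp (s) tags.
#' @return list of contour entries: `polygon` (n x 2 matrix, um), `z_um`,
#'   `t_s`, `label`, `hole`, `on_border`.
#' @export
extract_contours <- function(mask, pixel_um, z = NA_real_, t = NA_real_) {
  if (!any(mask)) return(list())
  xc <- px_coords(ncol(mask), pixel_um)
  yc <- px_coords(nrow(mask), pixel_um)
  # zero padding closes border-touching components along the border
  xp <- c(xc[1] - pixel_um, xc, xc[length(xc)] + pixel_um)
  yp <- c(yc[1] - pixel_um, yc, yc[length(yc)] + pixel_um)
  lab <- EBImage::bwlabel(mask * 1L)
  out <- list()
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    on_border <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)])
    padded <- matrix(0, nrow(comp) + 2, ncol(comp) + 2)
    padded[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
    cl <- contourLines(x = xp, y = yp, z = t(padded), levels = 0.5)
    # one component pixel centre, for hole orientation tests
    px <- which(comp, arr.ind = TRUE)[1, ]
    ppt <- matrix(c(xc[px[2]], yc[px[1]]), 1, 2)
    for (cc in cl) {
      poly <- cbind(cc$x, cc$y)
      if (nrow(poly) > 1 &&
          all(abs(poly[1, ] - poly[nrow(poly), ]) < 1e-12))
        poly <- poly[-nrow(poly), , drop = FALSE]
      if (nrow(poly) < 3) next
      # a loop NOT containing any material pixel of its component on its
      # inside is impossible; the loop containing the test pixel is the outer
      # ring unless the test pixel sits inside a hole loop as well -- decide
      # by enclosed area sign convention instead: orient all loops CCW first,
      # then holes are the loops whose interior point is background.
      a <- polygon_area(poly)
      if (a < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
      ctr <- polygon_centroid(poly)
      probe <- matrix(ctr, 1, 2)
      inside_mask <- {
        ix <- which.min(abs(xc - ctr[1])); iy <- which.min(abs(yc - ctr[2]))
        isTRUE(comp[iy, ix])
      }
      hole <- FALSE
      if (!inside_mask) {
        # centroid may fall outside for concave outer rings; classify by
        # whether the loop encloses the known material pixel
        encl <- .cpp_points_in_polygons(list(poly), ppt)
        hole <- !encl[1]
      }
      if (hole) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
      out[[length(out) + 1L]] <- list(polygon = poly, z_um = z, t_s = t,
                                      label = l, hole = hole,
                                      on_border = on_border)
    }
  }
  out
}

# rasterise a list of contour entries (or bare polygons) to a logical mask by
# the even-odd rule at pixel centres
rasterize_contours <- function(contours, width_px, height_px, pixel_um) {
  polys <- lapply(contours, function(e) if (is.list(e)) e$polygon else e)
  mask <- matrix(FALSE, height_px, width_px)
  if (!length(polys)) return(mask)
  xc <- px_coords(width_px, pixel_um)
  yc <- px_coords(height_px, pixel_um)
  G <- expand.grid(y = yc, x = xc)
  inside <- .cpp_points_in_polygons(polys, as.matrix(G[, c("x", "y")]))
  mask[matrix(inside, height_px, width_px)] <- TRUE
  mask
}

#' Reconstruct a watertight surface from a segmented z-stack
#'
#' Stacks the binary masks into a rectilinear volume (zero-padded on all
#' sides so the iso-surface closes), extracts the 0.5 iso-surface by
#' marching tetrahedra with the slice spacing from the metadata, caps the
#' mesh at the wall plane, and optionally applies the ripple filter.
#'
#' @param x a `segmented_stack`, a `zstack` (segmented with `threshold`), or
#'   a list of per-slice contour lists (rasterised first; needs `pixel_um`,
#'   `z_um` and image size attributes or arguments).
#' @param threshold used when `x` is a `zstack`.
#' @param smooth apply [ripple_filter()].
#' @param floor_z wall plane height (um); vertices below are clamped onto it.
#'   `NULL` disables capping (free-standing fixtures).
#' @param t_s provenance timestamp attached to the surface (default: median
#'   slice time).
#' @param ... passed to [ripple_filter()].
#' @return a watertight [tri_surface].
#' @export
build_surface <- function(x, threshold = "auto", smooth = TRUE, floor_z = 0,
                          t_s = NULL, ...) {
  if (inherits(x, "zstack")) x <- segment_stack(x, threshold = threshold)
  if (!inherits(x, "segmented_stack"))
    stopf("build_surface expects a zstack or segmented_stack")
  populated <- vapply(x$masks, any, logical(1))
  if (sum(populated) < 2)
    stopf("need at least 2 slices with non-empty masks (got %d)",
          sum(populated))
  if (smooth)
    ripple_filter(x, floor_z = floor_z, t_s = t_s, ...)
  else
    stack_binary_mesh(x, floor_z = floor_z, t_s = t_s)
}

# 0.5 iso-surface of the zero-padded binary mask volume, capped at the wall
stack_binary_mesh <- function(x, floor_z = 0, t_s = NULL) {
  nz <- length(x$masks)
  nxp <- x$width_px + 2L
  nyp <- x$height_px + 2L
  dz <- if (nz > 1) diff(x$z_um[1:2]) else 1
  vol <- array(0, dim = c(nxp, nyp, nz + 2L))
  for (k in seq_len(nz))
    vol[2:(nxp - 1), 2:(nyp - 1), k + 1] <- t(x$masks[[k]] * 1)
  xc <- px_coords(x$width_px, x$pixel_um)
  ys <- px_coords(x$height_px, x$pixel_um)
  xs <- c(xc[1] - x$pixel_um, xc, xc[length(xc)] + x$pixel_um)
  ys <- c(ys[1] - x$pixel_um, ys, ys[length(ys)] + x$pixel_um)
  zs <- c(x$z_um[1] - dz, x$z_um, x$z_um[nz] + dz)
  m <- .cpp_marching_tetrahedra(vol, xs, ys, zs, 0.5)
  V <- m$vertices
  if (!is.null(floor_z)) V[V[, 3] < floor_z, 3] <- floor_z
  tri_surface(V, m$faces,
              t_s = if (is.null(t_s)) stats::median(x$t_s) else t_s,
              floor_z = floor_z)
}

#' @rdname ripple_filter
#' @param passes number of (1, c, 1) z-smoothing passes over the
#'   signed-distance volume.
#' @param center_weight the c of the kernel: larger = gentler.
#' @param cap_um signed-distance saturation (um), bounding the influence of
#'   empty slices.
#' @param floor_z,t_s as in [build_surface()].
#' @export
ripple_filter.segmented_stack <- function(x, passes = 8, center_weight = 10,
                                          cap_um = 3, floor_z = 0,
                                          t_s = NULL, preserve_volume = TRUE,
                                          ...) {
  raw <- stack_binary_mesh(x, floor_z = floor_z, t_s = t_s)
  nz <- length(x$masks)
  dz <- if (nz > 1) diff(x$z_um[1:2]) else 1
  polys <- lapply(seq_len(nz), function(k) {
    cs <- extract_contours(x$masks[[k]], x$pixel_um, z = x$z_um[k],
                           t = x$t_s[k])
    lapply(cs, `[[`, "polygon")
  })
  pts <- do.call(rbind, unlist(polys, recursive = FALSE))
  xs_full <- px_coords(x$width_px, x$pixel_um)
  ys_full <- px_coords(x$height_px, x$pixel_um)
  marg <- 6 * x$pixel_um
  ix <- which(xs_full >= min(pts[, 1]) - marg & xs_full <= max(pts[, 1]) + marg)
  iy <- which(ys_full >= min(pts[, 2]) - marg & ys_full <= max(pts[, 2]) + marg)
  xs <- xs_full[ix]; ys <- ys_full[iy]
  sdf <- array(cap_um, dim = c(length(xs), length(ys), nz))
  for (k in seq_len(nz))
    if (length(polys[[k]]))
      sdf[, , k] <- pmin(pmax(contour_sdf(polys[[k]], xs, ys), -cap_um), cap_um)
  # z-smoothing, edge-replicated so the wall-contact slice is not eroded
  w <- c(1, center_weight, 1) / (center_weight + 2)
  for (p in seq_len(passes)) {
    lo <- sdf[, , c(1, seq_len(nz - 1))]
    hi <- sdf[, , c(seq_len(nz - 1) + 1, nz)]
    sdf <- w[1] * lo + w[2] * sdf + w[3] * hi
  }
  # pad with saturated outside values so the iso-surface closes
  nxp <- length(xs) + 2L; nyp <- length(ys) + 2L
  vol <- array(-cap_um, dim = c(nxp, nyp, nz + 2L))      # field = -sdf
  vol[2:(nxp - 1), 2:(nyp - 1), 2:(nz + 1)] <- -sdf
  xsp <- c(xs[1] - x$pixel_um, xs, xs[length(xs)] + x$pixel_um)
  ysp <- c(ys[1] - x$pixel_um, ys, ys[length(ys)] + x$pixel_um)
  zsp <- c(x$z_um[1] - dz, x$z_um, x$z_um[nz] + dz)
  m <- .cpp_marching_tetrahedra(vol, xsp, ysp, zsp, 0)
  V <- m$vertices
  if (!is.null(floor_z)) V[V[, 3] < floor_z, 3] <- floor_z
  out <- tri_surface(V, m$faces, t_s = raw$t_s, floor_z = floor_z)
  if (preserve_volume) out <- rescale_volume(out, mesh_volume(raw))
  out
}
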