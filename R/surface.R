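#' Triangulated thrombus surface
#'
#' Container for a triangulated surface in micrometre coordinates with
#' optional named per-vertex scalar channels and a provenance timestamp.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (um).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices,
#'   wound counter-clockwise seen from outside (outward normals).
#' @param scalars named list of per-vertex numeric vectors.
#' @param t_s provenance timestamp (s), `NA` if not tied to a timepoint.
#' @param floor_z height (um) of the wall plane the surface is capped at, or
#'   `NULL` for free-standing surfaces.
#' @return an object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, scalars = list(), t_s = NA_real_,
                        floor_z = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stopf("face indices out of range")
  for (nm in names(scalars))
    if (length(scalars[[nm]]) != nrow(vertices))
      stopf("scalar channel '%s' length does not match vertex count", nm)
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, faces = faces, scalars = scalars,
                 t_s = t_s, floor_z = floor_z),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  wt <- .cpp_edge_audit(x$faces)
  cat(sprintf("<tri_surface> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(wt$watertight)) ", watertight" else ", OPEN",
              if (is.finite(x$t_s)) sprintf(", t = %.3f s", x$t_s) else ""))
  if (length(x$scalars))
    cat("  scalar channels:", paste(names(x$scalars), collapse = ", "), "\n")
  invisible(x)
}

#' Watertightness audit
#'
#' A mesh is watertight (and consistently oriented) when every undirected
#' edge is shared by exactly two triangles, once in each direction.
#'
#' @param surface a [tri_surface].
#' @return list with `watertight`, `n_boundary_edges`, `n_nonmanifold_edges`.
#' @export
is_watertight <- function(surface) .cpp_edge_audit(surface$faces)

#' Enclosed volume of a watertight surface
#'
#' Signed-tetrahedron (divergence theorem) sum; positive for outward-oriented
#' meshes.
#'
#' @param surface a [tri_surface].
#' @return volume in um^3.
#' @export
mesh_volume <- function(surface) .cpp_mesh_volume(surface$vertices, surface$faces)

#' Area-weighted outward vertex normals
#' @param surface a [tri_surface].
#' @return matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(surface) .cpp_vertex_normals(surface$vertices, surface$faces)

#' Per-vertex surface area (one third of incident triangle areas)
#' @param surface a [tri_surface].
#' @return numeric vector, um^2 per vertex.
#' @export
vertex_areas <- function(surface) .cpp_vertex_areas(surface$vertices, surface$faces)

#' Summary metrics of a reconstructed surface
#'
#' Volume by the divergence theorem and bounding-box extents with length
#' along the flow direction (x), width across the channel (y) and height
#' above the wall (z).
#'
#' @param surface a watertight [tri_surface].
#' @return a one-row tibble: `volume_um3`, `length_um`, `width_um`,
#'   `height_um`.
#' @export
surface_metrics <- function(surface) {
  wt <- .cpp_edge_audit(surface$faces)
  if (!isTRUE(wt$watertight))
    stopf(paste0("surface is not watertight: %d boundary edge(s), ",
                 "%d non-manifold edge(s)"),
          wt$n_boundary_edges, wt$n_nonmanifold_edges)
  v <- surface$vertices
  tibble::tibble(
    volume_um3 = mesh_volume(surface),
    length_um = max(v[, 1]) - min(v[, 1]),
    width_um = max(v[, 2]) - min(v[, 2]),
    height_um = max(v[, 3]) - min(v[, 3]))
}

#' Attenuate inter-slice ripple artefacts
#'
#' Stacked confocal reconstruction leaves oscillations between z-slices
#' ("ripples"). The filter is generic over the input:
#'
#' For a `segmented_stack` (or instantaneous stack) the masks are converted
#' to per-slice signed-distance fields, the fields are smoothed along z with
#' a narrow (1, c, 1) kernel (edge-replicated at the ends so the wall contact
#' is not eroded), and the zero level is re-meshed: the ripple is the highest
#' z-frequency of that signal, so it is attenuated strongly while in-plane
#' detail is untouched. This is the path [build_surface()] uses.
#'
#' For a bare [tri_surface] a gentle Taubin lambda/mu pass with z-biased
#' neighbour weights is applied (smooth inputs pass nearly unchanged).
#'
#' Both paths rescale the result about its centroid (x, y) and the wall plane
#' (z) so the enclosed volume matches the unfiltered surface (well within the
#' 1 percent contract).
#'
#' @param x a watertight [tri_surface] or a `segmented_stack`.
#' @param ... passed to methods.
#' @return the filtered [tri_surface].
#' @export
ripple_filter <- function(x, ...) UseMethod("ripple_filter")

#' @rdname ripple_filter
#' @param iterations number of Taubin lambda/mu passes.
#' @param lambda,mu Taubin parameters (`0 < lambda`, `mu < -lambda` shrinks
#'   then re-inflates, limiting net shrinkage).
#' @param z_weight extra weight given to z-crossing edges (0 = isotropic).
#' @param preserve_volume rescale so the volume is preserved.
#' @export
ripple_filter.tri_surface <- function(x, iterations = 10, lambda = 0.5,
                                      mu = -0.53, z_weight = 2,
                                      preserve_volume = TRUE, ...) {
  v0 <- mesh_volume(x)
  pin <- if (!is.null(x$floor_z))
    x$vertices[, 3] <= x$floor_z + 1e-9
  else rep(FALSE, nrow(x$vertices))
  V <- .cpp_taubin_smooth(x$vertices, x$faces, as.integer(iterations),
                          lambda, mu, z_weight, pin)
  out <- x
  out$vertices <- V
  colnames(out$vertices) <- c("x", "y", "z")
  if (preserve_volume) out <- rescale_volume(out, v0)
  out
}

# uniform rescale about (centroid_x, centroid_y, floor_z) to a target volume
rescale_volume <- function(surface, v_target) {
  v1 <- mesh_volume(surface)
  if (v1 <= 0 || v_target <= 0) return(surface)
  s <- (v_target / v1)^(1 / 3)
  V <- surface$vertices
  cx <- mean(V[, 1]); cy <- mean(V[, 2])
  z0 <- if (!is.null(surface$floor_z)) surface$floor_z else mean(V[, 3])
  surface$vertices[, 1] <- cx + s * (V[, 1] - cx)
  surface$vertices[, 2] <- cy + s * (V[, 2] - cy)
  surface$vertices[, 3] <- z0 + s * (V[, 3] - z0)
  surface
}

# connected components of a mesh (vertex-connectivity union-find);
# returns integer component id per vertex
mesh_components <- function(surface) {
  n <- nrow(surface$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  F <- surface$faces
  for (t in seq_len(nrow(F))) {
    a <- find(F[t, 1]); b <- find(F[t, 2]); c <- find(F[t, 3])
    parent[b] <- a; parent[c] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# extract sub-surface of one component, keeping scalar channels
mesh_subset <- function(surface, keep_vertices) {
  idx <- which(keep_vertices)
  remap <- rep(NA_integer_, nrow(surface$vertices))
  remap[idx] <- seq_along(idx)
  keep_face <- keep_vertices[surface$faces[, 1]] &
    keep_vertices[surface$faces[, 2]] & keep_vertices[surface$faces[, 3]]
  F <- surface$faces[keep_face, , drop = FALSE]
  F[] <- remap[F]
  tri_surface(surface$vertices[idx, , drop = FALSE], F,
              scalars = lapply(surface$scalars, function(s) s[idx]),
              t_s = surface$t_s, floor_z = surface$floor_z)
}
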