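# File formats: multi-page TIFF + JSON sidecar for z-stacks, PLY (ascii or
# binary little-endian, with named per-vertex float scalars) and ascii STL
# for surfaces, legacy VTK rectilinear grids for flow/shear fields.

#' Write / read a z-stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored in a 16-bit TIFF container (one page per slice,
#' bottom-up z order); the sidecar records the true bit depth, pixel size and
#' per-slice z/t metadata. Round trips are bit-identical.
#'
#' @param stack a `zstack`.
#' @param tiff_path,json_path output paths (json defaults to the tiff path
#'   with extension .json).
#' @return `write_zstack`: the paths, invisibly. `read_zstack`: a `zstack`.
#' @export
write_zstack <- function(stack, tiff_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.tiff?$", ".json", tiff_path)
  pages <- lapply(stack$slices, function(s) s / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  meta <- list(stack_index = stack$stack_index,
               pixel_size_um = stack$pixel_um,
               bit_depth = stack$bit_depth,
               slices = data.frame(z_um = stack$z_um, t_s = stack$t_s))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tiff_path, json = json_path))
}

#' @rdname write_zstack
#' @export
read_zstack <- function(tiff_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.tiff?$", ".json", tiff_path)
  if (!file.exists(json_path)) stopf("missing metadata sidecar '%s'", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (fld in c("pixel_size_um", "bit_depth", "slices"))
    if (is.null(meta[[fld]])) stopf("metadata missing field '%s'", fld)
  if (is.null(meta$slices$z_um) || is.null(meta$slices$t_s))
    stopf("metadata slices must record z_um and t_s")
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  slices <- lapply(pages, function(p) {
    m <- round(p * 65535)
    storage.mode(m) <- "integer"
    m
  })
  zstack(slices, z_um = meta$slices$z_um, t_s = meta$slices$t_s,
         pixel_um = meta$pixel_size_um, bit_depth = meta$bit_depth,
         stack_index = if (is.null(meta$stack_index)) 1L else meta$stack_index)
}

#' Write a surface to PLY or STL
#'
#' Format chosen by extension: `.ply` (binary little-endian by default, with
#' per-vertex float scalar channels as named properties) or `.stl` (ascii,
#' geometry only -- scalar channels are dropped).
#'
#' @param surface a [tri_surface].
#' @param path output path.
#' @param binary for PLY: binary little-endian (default) or ascii.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(surface, path, binary = binary),
         stl = write_stl(surface, path),
         stopf("unsupported surface format '.%s' (use .ply or .stl)", ext))
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         stl = read_stl(path),
         stopf("unsupported surface format '.%s' (use .ply or .stl)", ext))
}

write_ply <- function(surface, path, binary = TRUE) {
  nv <- nrow(surface$vertices); nf <- nrow(surface$faces)
  sc <- surface$scalars
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              "comment thromboflow surface",
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("property float %s", names(sc)),
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  vdat <- cbind(surface$vertices,
                if (length(sc)) do.call(cbind, sc) else NULL)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.numeric(t(vdat)), con, size = 4, endian = "little")
    fdat <- t(cbind(3L, surface$faces - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.integer(3L), con, size = 1, endian = "little")
      writeBin(as.integer(surface$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(vdat, 1, function(r) paste(format(r, digits = 9),
                                                collapse = " ")), con)
    writeLines(apply(surface$faces - 1L, 1,
                     function(r) paste(c(3L, r), collapse = " ")), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1)
    header <- c(header, ln)
    if (identical(ln, "end_header")) break
    if (length(header) > 200) stopf("malformed PLY header in '%s'", path)
  }
  fmt <- grep("^format", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  vi <- grep("^element vertex", header)
  fi <- grep("^element face", header)
  vprops <- sub("^property \\S+ ", "", grep("^property", header[(vi + 1):(fi - 1)], value = TRUE))
  np <- length(vprops)
  if (binary) {
    vdat <- matrix(readBin(con, "numeric", n = nv * np, size = 4,
                           endian = "little"), ncol = np, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3) stopf("non-triangular face in '%s'", path)
      faces[i, ] <- idx + 1L
    }
  } else {
    txt <- readLines(con)
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(txt[seq_len(nv)]), "\\s+"))),
                   ncol = np, byrow = TRUE)
    frows <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(frows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
  }
  scal <- list()
  if (np > 3)
    for (j in 4:np) scal[[vprops[j]]] <- vdat[, j]
  tri_surface(vdat[, 1:3, drop = FALSE], faces, scalars = scal)
}

write_stl <- function(surface, path) {
  if (length(surface$scalars))
    warning("STL stores geometry only: scalar channels dropped")
  V <- surface$vertices; F <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid thromboflow", con)
  for (i in seq_len(nrow(F))) {
    p <- V[F[i, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid thromboflow", con)
  invisible(path)
}

read_stl <- function(path) {
  txt <- readLines(path)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  coords <- matrix(as.numeric(unlist(strsplit(trimws(sub("\\s*vertex\\s+", "", vl)),
                                              "\\s+"))), ncol = 3, byrow = TRUE)
  # weld identical vertices so the mesh is indexed
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  V <- coords[uniq, , drop = FALSE]
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  warning("STL carries no scalar channels")
  tri_surface(V, F)
}

#' Write flow and shear fields as a legacy VTK rectilinear grid
#'
#' Cell-centred velocity (m/s), pressure (Pa) and local shear rate (1/s) on
#' the cell-centre coordinates (um), readable by ParaView/VisIt.
#'
#' @param field a `flow_field`.
#' @param path output path (.vtk).
#' @param shear optional matching `shear_field`.
#' @return the path, invisibly.
#' @export
write_field_vtk <- function(field, path, shear = NULL) {
  g <- field$grid
  nx <- length(g$xc); ny <- length(g$yc); nz <- length(g$zc)
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(format(x, digits = 9), collapse = " ")
  writeLines(c("# vtk DataFile Version 3.0",
               "thromboflow flow field (um grid, m/s velocity)",
               "ASCII", "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("X_COORDINATES %d float", nx), num(g$xc),
               sprintf("Y_COORDINATES %d float", ny), num(g$yc),
               sprintf("Z_COORDINATES %d float", nz), num(g$zc),
               sprintf("POINT_DATA %d", nx * ny * nz),
               "VECTORS velocity float"), con)
  U <- cbind(as.vector(field$uc), as.vector(field$vc), as.vector(field$wc))
  writeLines(apply(U, 1, num), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(vapply(as.vector(field$p), function(x) format(x, digits = 9), ""), con)
  if (!is.null(shear)) {
    writeLines(c("SCALARS gamma_local float 1", "LOOKUP_TABLE default"), con)
    writeLines(vapply(as.vector(shear$gamma), function(x) format(x, digits = 9), ""), con)
  }
  invisible(path)
}

#' Export a growth map as CSV
#'
#' Per-vertex rows (x, y, z, signed distance, label).
#' @param map a [growth_map()].
#' @param path output csv path.
#' @param threshold passed to [classify_growth()].
#' @return the path, invisibly.
#' @export
write_growth_csv <- function(map, path, threshold = 0.5) {
  V <- map$surface$vertices
  df <- data.frame(x = V[, 1], y = V[, 2], z = V[, 3],
                   growth_um = map$distance,
                   label = as.character(classify_growth(map, threshold)),
                   status = map$status)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export pathlines as CSV
#'
#' Long-format rows (pathline id, elapsed t, x, y, z, gamma).
#' @param paths list of `pathline` objects.
#' @param path output csv path.
#' @return the path, invisibly.
#' @export
write_pathlines_csv <- function(paths, path) {
  rows <- do.call(rbind, lapply(seq_along(paths), function(i) {
    s <- paths[[i]]$samples
    data.frame(pathline = i, t_s = s$t, x_um = s$x, y_um = s$y, z_um = s$z,
               gamma = s$gamma, termination = paths[[i]]$termination)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
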