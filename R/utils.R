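# shared small helpers

# run expr with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

# pixel-centre coordinates (um) for n pixels, centred about 0
px_coords <- function(n, pixel_um) (seq_len(n) - (n + 1) / 2) * pixel_um

# shoelace signed area of a polygon (matrix with columns x, y)
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  0.5 * sum(x[j] * y - x * y[j])
}

polygon_centroid <- function(p) {
  a <- polygon_area(p)
  if (abs(a) < 1e-12) return(colMeans(p[, 1:2, drop = FALSE]))
  n <- nrow(p); x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  c(sum((x[j] + x) * cr), sum((y[j] + y) * cr)) / (6 * a)
}
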