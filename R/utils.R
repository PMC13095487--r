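# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Wrap an angle into (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# Angle of the vector `from` -> `to` in image coordinates (row, col), with
# x = col and y = -row so that "up" (decreasing row) is +pi/2 and "right"
# (increasing col) is 0.
point_angle <- function(from, to) {
  atan2(-(to[1] - from[1]), to[2] - from[2])
}

# Integer pixels of the straight segment p0 -> p1 (both (row, col)),
# endpoints included. Bresenham-style supercover via dense sampling.
bresenham <- function(p0, p1) {
  n <- max(abs(p1 - p0))
  if (n < 1) return(matrix(round(p0), 1, 2))
  t <- seq(0, 1, length.out = ceiling(n) + 1)
  px <- cbind(round(p0[1] + t * (p1[1] - p0[1])),
              round(p0[2] + t * (p1[2] - p0[2])))
  px[!duplicated(px), , drop = FALSE]
}

# Disc offsets (row, col) for integer radius-ball of given (possibly
# fractional) radius around a pixel centre.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Stamp value into matrix `m` at discs of `radius` around points (n x 2).
stamp_discs <- function(m, points, radius, value = TRUE) {
  if (nrow(points) == 0) return(m)
  off <- disc_offsets(radius)
  nr <- nrow(m); nc <- ncol(m)
  r <- rep(points[, 1], each = nrow(off)) + rep(off[, 1], nrow(points))
  c <- rep(points[, 2], each = nrow(off)) + rep(off[, 2], nrow(points))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  m[cbind(r[ok], c[ok])] <- value
  m
}

# Arc length (pixels) of a polyline given as an n x 2 matrix.
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Resample a polyline at (approximately) even arc-length spacing `step`,
# always retaining both endpoints. Returns an m x 2 matrix.
resample_polyline <- function(pts, step) {
  L <- polyline_length(pts)
  if (L <= step) return(pts[c(1, nrow(pts)), , drop = FALSE])
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  tt <- seq(0, L, length.out = max(2, ceiling(L / step) + 1))
  cbind(approx(s, pts[, 1], xout = tt)$y, approx(s, pts[, 2], xout = tt)$y)
}

# Sub-polyline between arc-length fractions f0 < f1 (exact interpolation at
# the cut points).
polyline_section <- function(pts, f0, f1) {
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- s[length(s)]
  a <- f0 * L; b <- f1 * L
  interp <- function(at) {
    c(approx(s, pts[, 1], xout = at)$y, approx(s, pts[, 2], xout = at)$y)
  }
  inner <- which(s > a & s < b)
  out <- rbind(interp(a), pts[inner, , drop = FALSE], interp(b))
  out[!duplicated(round(out, 9)), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Global linear pixel indices of a disc-swept polyline stroke, computed on
# a bounding-box crop (cheap on large canvases).
stroke_pixel_set <- function(polyline, radius, image_size) {
  pad <- radius + 1
  r0 <- max(1, floor(min(polyline[, 1]) - pad))
  c0 <- max(1, floor(min(polyline[, 2]) - pad))
  r1 <- min(image_size[1], ceiling(max(polyline[, 1]) + pad))
  c1 <- min(image_size[2], ceiling(max(polyline[, 2]) + pad))
  local <- rasterize_stroke(sweep(polyline, 2, c(r0 - 1, c0 - 1)), radius,
                            c(r1 - r0 + 1, c1 - c0 + 1))
  idx <- which(local, arr.ind = TRUE)
  sort((idx[, 2] + c0 - 2) * image_size[1] + idx[, 1] + r0 - 1)
}
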