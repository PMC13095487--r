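# Pluggable per-pixel 3-class segmentation with tiled whole-image inference,
# test-time augmentation and ensembling.
#
# A segmentation backend is a function mapping a rows x cols x 2 intensity
# array to a rows x cols x 3 per-class probability array (background,
# analog 1, analog 2) with per-pixel sums equal to 1. Backends declare a
# preferred receptive patch size via the "patch_size" attribute. A learned
# model satisfying this contract can be plugged in; the package ships a
# transparent intensity-threshold backend.

#' Intensity-threshold segmentation backend
#'
#' Assigns analog classes by channel dominance among supra-threshold pixels
#' after light smoothing. Probabilities are formed by normalizing the
#' per-channel margins above threshold together with a background margin, so
#' they are soft near the threshold and saturate on clean strokes.
#'
#' @param threshold `"otsu"` for a per-channel Otsu threshold, or a numeric
#'   length-2 vector of fixed thresholds on the intensity scale.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (0 disables).
#' @param patch_size declared receptive patch size (pixels).
#' @return a backend function of class `seg_backend`.
#' @export
threshold_backend <- function(threshold = "otsu", smooth_sigma = 1,
                              patch_size = 1024L) {
  fixed <- NULL
  if (is.numeric(threshold)) {
    if (length(threshold) == 1) threshold <- rep(threshold, 2)
    fixed <- threshold
  } else if (!identical(threshold, "otsu")) {
    stop("threshold must be \"otsu\" or numeric")
  }
  f <- function(patch) {
    stopifnot(length(dim(patch)) == 3, dim(patch)[3] == 2)
    s <- lapply(1:2, function(k) {
      x <- patch[, , k]
      if (smooth_sigma > 0 && min(dim(x)) > 4)
        x <- EBImage::gblur(x, smooth_sigma)
      x
    })
    thr <- if (!is.null(fixed)) fixed else vapply(s, function(x) {
      mx <- max(x)
      if (mx <= 0) return(0.5)
      EBImage::otsu(x / mx, range = c(0, 1)) * mx
    }, numeric(1))
    a1 <- pmax(s[[1]] - thr[1], 0)
    a2 <- pmax(s[[2]] - thr[2], 0)
    bg <- pmax(pmin(thr[1] - s[[1]], thr[2] - s[[2]]), 0) + 1e-6
    tot <- a1 + a2 + bg
    out <- array(0, c(dim(patch)[1:2], 3))
    out[, , 1] <- bg / tot
    out[, , 2] <- a1 / tot
    out[, , 3] <- a2 / tot
    out
  }
  structure(f, patch_size = as.integer(patch_size), class = "seg_backend")
}

#' Tiling specification for whole-image inference
#'
#' @param tile tile side in pixels (default 1024).
#' @param overlap_fraction fractional overlap between adjacent tiles
#'   (default 0.10, must be in `[0, 0.5)`).
#' @param blend_sigma Gaussian blending sigma as a fraction of the tile side.
#' @return named list of class `tile_spec`.
#' @export
tile_spec <- function(tile = 1024L, overlap_fraction = 0.10,
                      blend_sigma = 0.125) {
  if (tile <= 0) stop("tile must be > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must be in [0, 0.5)")
  structure(list(tile = as.integer(tile),
                 overlap_fraction = overlap_fraction,
                 blend_sigma = blend_sigma), class = "tile_spec")
}

reflect_pad <- function(arr, pad_r, pad_c) {
  d <- dim(arr)
  idx_r <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(d[1] + pad_r)]
  idx_c <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(d[2] + pad_c)]
  arr[idx_r, idx_c, , drop = FALSE]
}

tile_starts <- function(n, tile, stride) {
  if (n <= tile) return(1L)
  s <- seq(1L, n - tile + 1L, by = stride)
  if (s[length(s)] != n - tile + 1L) s <- c(s, n - tile + 1L)
  s
}

#' Tiled whole-image inference with Gaussian blending
#'
#' The image is split into overlapping tiles; each tile is passed to the
#' backend and the per-class probabilities are recombined by a weighted
#' average with an isotropic Gaussian weight centred on each tile, so that
#' predictions near tile centres dominate and overlaps blend smoothly.
#' Images smaller than one tile are reflect-padded. Because the weights are
#' strictly positive and the per-tile maps lie on the probability simplex,
#' the blended map does too.
#'
#' @param backend a segmentation backend function.
#' @param img a [fluor_image] or rows x cols x 2 array.
#' @param spec a [tile_spec()].
#' @return rows x cols x 3 probability array.
#' @export
tiled_inference <- function(backend, img, spec = tile_spec()) {
  arr <- if (inherits(img, "fluor_image")) img$data else img
  d0 <- dim(arr)[1:2]
  T <- spec$tile
  pad <- pmax(0L, T - d0)
  if (any(pad > 0)) arr <- reflect_pad(arr, pad[1], pad[2])
  d <- dim(arr)[1:2]
  stride <- max(1L, as.integer(round(T * (1 - spec$overlap_fraction))))
  rs <- tile_starts(d[1], T, stride)
  cs <- tile_starts(d[2], T, stride)
  sig <- spec$blend_sigma * T
  g <- exp(-((seq_len(T) - (T + 1) / 2)^2) / (2 * sig^2))
  w <- outer(g, g)
  num <- array(0, c(d, 3))
  den <- matrix(0, d[1], d[2])
  for (r0 in rs) for (c0 in cs) {
    ri <- r0:(r0 + T - 1L); ci <- c0:(c0 + T - 1L)
    p <- backend(arr[ri, ci, , drop = FALSE])
    for (k in 1:3) num[ri, ci, k] <- num[ri, ci, k] + p[, , k] * w
    den[ri, ci] <- den[ri, ci] + w
  }
  out <- array(0, c(d0, 3))
  for (k in 1:3) out[, , k] <- (num[, , k] / den)[seq_len(d0[1]),
                                                 seq_len(d0[2])]
  out
}

# The 8 dihedral transforms of a square raster and their inverses; for
# non-square inputs only the 4 axis-preserving ones (identity, row flip,
# column flip, 180 degree rotation) are usable.
d4_transforms <- function(square) {
  flip_r <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  flip_c <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  transp <- function(a) {
    out <- array(0, c(dim(a)[2], dim(a)[1], dim(a)[3]))
    for (k in seq_len(dim(a)[3])) out[, , k] <- t(a[, , k])
    out
  }
  rot180 <- function(a) flip_r(flip_c(a))
  tf <- list(
    list(fwd = identity, inv = identity),
    list(fwd = flip_r, inv = flip_r),
    list(fwd = flip_c, inv = flip_c),
    list(fwd = rot180, inv = rot180))
  if (square) {
    rot90 <- function(a) flip_r(transp(a))          # 90 deg clockwise
    rot270 <- function(a) flip_c(transp(a))
    tf <- c(tf, list(
      list(fwd = rot90, inv = rot270),
      list(fwd = rot270, inv = rot90),
      list(fwd = transp, inv = transp),
      list(fwd = function(a) rot180(transp(a)),
           inv = function(a) rot180(transp(a)))))
  }
  tf
}

#' Test-time augmentation
#'
#' Averages backend predictions over geometric transforms of the input:
#' the full 8-element dihedral group for square images, flips and 180-degree
#' rotation for non-square ones. Equivariant backends are unchanged by TTA.
#'
#' @param backend a segmentation backend.
#' @param img a [fluor_image] or rows x cols x 2 array.
#' @return rows x cols x 3 probability array.
#' @export
tta_inference <- function(backend, img) {
  arr <- if (inherits(img, "fluor_image")) img$data else img
  tf <- d4_transforms(dim(arr)[1] == dim(arr)[2])
  maps <- lapply(tf, function(t) t$inv(backend(t$fwd(arr))))
  Reduce(`+`, maps) / length(maps)
}

#' Ensemble inference
#'
#' Unweighted pixel-wise mean of the probability maps of several backends.
#'
#' @param backends non-empty list of segmentation backends.
#' @param img a [fluor_image] or rows x cols x 2 array.
#' @return rows x cols x 3 probability array.
#' @export
ensemble_inference <- function(backends, img) {
  if (length(backends) == 0) stop("ensemble requires at least one backend")
  arr <- if (inherits(img, "fluor_image")) img$data else img
  maps <- lapply(backends, function(b) b(arr))
  Reduce(`+`, maps) / length(maps)
}

#' Class mask from a probability map
#'
#' Per-pixel argmax over (background, analog 1, analog 2); ties resolve to
#' the lowest class index.
#'
#' @param prob rows x cols x 3 probability array.
#' @return integer matrix with values in `{0, 1, 2}`.
#' @export
prob_to_mask <- function(prob) {
  d <- dim(prob)
  m <- matrix(0L, d[1], d[2])
  best <- prob[, , 1]
  for (k in 2:3) {
    sel <- prob[, , k] > best
    m[sel] <- k - 1L
    best[sel] <- prob[, , k][sel]
  }
  m
}

#' Run segmentation on a whole image
#'
#' Convenience wrapper: applies the backend directly when the image fits in
#' a single tile, tiled inference otherwise; optional test-time
#' augmentation (per tile for large images).
#'
#' @param img a [fluor_image].
#' @param backend a segmentation backend (or list of backends to ensemble).
#' @param spec a [tile_spec()].
#' @param tta logical, average over geometric transforms.
#' @return rows x cols x 3 probability array.
#' @export
segment_image <- function(img, backend = threshold_backend(),
                          spec = tile_spec(), tta = FALSE) {
  base <- if (is.list(backend) && !inherits(backend, "seg_backend")) {
    bl <- backend
    structure(function(a) ensemble_inference(bl, a),
              patch_size = attr(bl[[1]], "patch_size") %||% spec$tile)
  } else backend
  eff <- if (tta) {
    structure(function(a) tta_inference(base, a),
              patch_size = attr(base, "patch_size"))
  } else base
  d <- dim(img)
  if (all(d <= spec$tile)) eff(img$data) else tiled_inference(eff, img, spec)
}
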