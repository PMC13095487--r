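# Image preprocessing: pixel-size standardization and per-channel
# background-subtracted contrast normalization to 8 bits.

#' Preprocessing parameters
#'
#' @param target_pixel_size target resolution in micrometres per pixel; the
#'   fixed working scale of the analysis (default 0.26).
#' @param clarity background-subtraction strength alpha in `[0, 1]`. `1` is
#'   full subtraction; `0` disables subtraction and percentile clipping.
#' @param downsample_factor integer downsampling of the background proxy.
#' @param median_kernel median-filter window (pixels, odd) at proxy scale.
#' @param percentile_stride subsampling stride used when estimating the
#'   rescaling percentile.
#' @return named list of class `prep_params`.
#' @export
prep_params <- function(target_pixel_size = 0.26, clarity = 1,
                        downsample_factor = 8, median_kernel = 31,
                        percentile_stride = 4) {
  if (clarity < 0 || clarity > 1) stop("clarity must be in [0, 1]")
  if (target_pixel_size <= 0) stop("target_pixel_size must be > 0")
  structure(list(target_pixel_size = target_pixel_size, clarity = clarity,
                 downsample_factor = downsample_factor,
                 median_kernel = median_kernel,
                 percentile_stride = percentile_stride),
            class = "prep_params")
}

#' Rescale an image to the standard pixel size
#'
#' Bilinear resampling so that the output pixel size equals
#' `params$target_pixel_size`. A no-op when the sizes already agree to 1e-6.
#'
#' @param img a [fluor_image] with known `pixel_size`.
#' @param params a [prep_params()].
#' @return the rescaled [fluor_image].
#' @export
rescale_to_pixel_size <- function(img, params = prep_params()) {
  if (is.na(img$pixel_size) || img$pixel_size <= 0)
    stop("image pixel size unknown; supply pixel_size when reading the image")
  if (abs(img$pixel_size - params$target_pixel_size) < 1e-6) return(img)
  f <- img$pixel_size / params$target_pixel_size
  d <- dim(img)
  nd <- pmax(1, round(d * f))
  out <- fluor_image(
    EBImage::resize(img_channel(img, 1), w = nd[1], h = nd[2]),
    EBImage::resize(img_channel(img, 2), w = nd[1], h = nd[2]),
    pixel_size = params$target_pixel_size)
  out
}

# Percentile of a strided subsample (deterministic; exactness not needed,
# only reproducibility and memory economy on large mosaics).
strided_percentile <- function(x, prob, stride) {
  sub <- x[seq(1, nrow(x), by = stride), seq(1, ncol(x), by = stride)]
  quantile(sub, probs = prob, names = FALSE, type = 7)
}

# Smooth background estimate: median filter on a downsampled proxy,
# upsampled back to full resolution.
estimate_background <- function(v, params) {
  d <- dim(v)
  pd <- pmax(4, round(d / params$downsample_factor))
  proxy <- EBImage::resize(v, w = pd[1], h = pd[2])
  half <- max(1, floor(params$median_kernel / 2))
  half <- min(half, floor((min(pd) - 1) / 2))
  rng <- range(proxy)
  # EBImage::medianFilter expects values in [0,1]
  scaled <- if (diff(rng) > 0) (proxy - rng[1]) / diff(rng) else proxy * 0
  med <- EBImage::medianFilter(scaled, size = half)
  med <- med * diff(rng) + rng[1]
  EBImage::resize(med, w = d[1], h = d[2])
}

#' Normalize a fluorescence image to background-subtracted 8-bit
#'
#' Per channel: intensities are scaled to `[0, 1]`; a smooth background is
#' estimated by median-filtering a downsampled proxy and upsampled back; the
#' background is subtracted with strength `clarity` (alpha) and clipped at
#' zero; the result is rescaled so that the `p(100 - alpha)` percentile
#' (p99 at alpha = 1, the max at alpha = 0) maps to 255, then clipped and
#' rounded to 8-bit integers.
#'
#' @param img a [fluor_image].
#' @param params a [prep_params()].
#' @return a [fluor_image] with integer-valued data in `[0, 255]`.
#' @export
normalize_image <- function(img, params = prep_params()) {
  a <- params$clarity
  prob <- (100 - a) / 100
  out <- lapply(1:2, function(k) {
    x <- img_channel(img, k)
    mx <- max(x)
    v <- if (mx > 0) x / mx else x
    bg <- estimate_background(v, params)
    corr <- pmax(v - a * bg, 0)
    q <- strided_percentile(corr, prob, params$percentile_stride)
    # floor the rescale percentile at 1% of the dynamic range: on sparse
    # high-contrast images the upper percentile can land in numerical
    # residue of the background model and would amplify it to full scale
    q <- max(q, 0.01 * max(corr))
    if (q <= 0) return(matrix(0, nrow(x), ncol(x)))
    clamp(round(corr / q * 255), 0, 255)
  })
  fluor_image(out[[1]], out[[2]], pixel_size = img$pixel_size)
}
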