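#' Two-channel fluorescence image
#'
#' Container for a dual-channel DNA fiber spreading image. Channel 1 holds
#' the first analog (CldU, conventionally shown red), channel 2 the second
#' analog (IdU, green). All geometry in the package is expressed in pixel
#' units as `(row, col)` with the pixel centre at integer coordinates;
#' physical lengths are obtained by multiplying by `pixel_size` (micrometres
#' per pixel).
#'
#' @param ch1,ch2 numeric matrices of identical dimension; intensities of the
#'   first / second analog channel.
#' @param pixel_size micrometres per pixel, or `NA` if unknown.
#' @return An object of class `fluor_image`: a list with elements `data`
#'   (numeric array `rows x cols x 2`) and `pixel_size`.
#' @export
fluor_image <- function(ch1, ch2, pixel_size = NA_real_) {
  ch1 <- as.matrix(ch1); ch2 <- as.matrix(ch2)
  if (!all(dim(ch1) == dim(ch2))) stop("channel dimensions differ")
  if (any(dim(ch1) == 0)) stop("zero-size image")
  if (!all(is.finite(ch1)) || !all(is.finite(ch2)))
    stop("image contains non-finite values")
  data <- array(0, c(dim(ch1), 2))
  data[, , 1] <- ch1; data[, , 2] <- ch2
  structure(list(data = data, pixel_size = pixel_size),
            class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fluor_image> %d x %d px, 2 channels, pixel size %s um/px\n",
              d[1], d[2],
              if (is.na(x$pixel_size)) "unknown" else
                format(x$pixel_size)))
  invisible(x)
}

#' @export
dim.fluor_image <- function(x) dim(x$data)[1:2]

img_channel <- function(img, k) img$data[, , k]

#' Read a fluorescence image from TIFF or PNG
#'
#' Reads a dual-channel file, or merges two single-channel files. For files
#' with 3+ channels the first two are used (in the configured order).
#'
#' @param path path to a 2+ channel TIFF/PNG, or the channel-1 file when
#'   `path2` is given.
#' @param path2 optional path of the channel-2 file.
#' @param pixel_size micrometres per pixel of the acquisition.
#' @param channel_order length-2 integer; which file channel is analog 1 and
#'   analog 2 respectively. Default `c(1, 2)`.
#' @return a [fluor_image]. Intensities are rescaled to the 0--255 range.
#' @export
read_fluor_image <- function(path, path2 = NULL, pixel_size = NA_real_,
                             channel_order = c(1, 2)) {
  read_one <- function(p) {
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      # libtiff flags the second gray channel as an "extra sample"; the
      # data are read correctly, so that specific warning is muffled
      withCallingHandlers(
        tiff::readTIFF(p, all = FALSE),
        warning = function(w) {
          if (grepl("ExtraSamples", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    } else if (grepl("\\.png$", p, ignore.case = TRUE)) {
      png::readPNG(p)
    } else stop("unsupported image format: ", p)
  }
  if (!is.null(path2)) {
    a <- read_one(path); b <- read_one(path2)
    if (length(dim(a)) == 3) a <- a[, , 1]
    if (length(dim(b)) == 3) b <- b[, , 1]
    chans <- list(a, b)[order(channel_order)]
  } else {
    x <- read_one(path)
    if (length(dim(x)) != 3 || dim(x)[3] < 2)
      stop("expected a 2+ channel image in ", path)
    chans <- list(x[, , channel_order[1]], x[, , channel_order[2]])
  }
  # readTIFF/readPNG return [0,1]; bring to 8-bit scale
  fluor_image(chans[[1]] * 255, chans[[2]] * 255, pixel_size = pixel_size)
}

#' Write a fluorescence image as a 2-channel TIFF
#'
#' @param img a [fluor_image] (values on the 0--255 scale).
#' @param path output path (`.tif`/`.tiff`).
#' @export
write_fluor_image <- function(img, path) {
  arr <- clamp(img$data / 255, 0, 1)
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a class mask as an indexed PNG
#'
#' Pixel values 0 (background), 1 (analog 1), 2 (analog 2) are stored as
#' gray levels 0, 1, 2 in an 8-bit single-channel PNG.
#'
#' @param mask integer matrix with values in `{0, 1, 2}`.
#' @param path output path.
#' @export
write_seg_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a class mask written by [write_seg_mask()]
#' @param path PNG path.
#' @return integer matrix with values in `{0, 1, 2}`.
#' @export
read_seg_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
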