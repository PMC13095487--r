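# In-silico controls: fiber shortening with annulus inpainting plus the
# analytic ratio expectation, and image degradation by blur or noise.

#' Expected ratio after cutting fiber ends
#'
#' If a fiber population has second/first analog ratio `alpha` and a
#' fraction `c_r` of every first-analog (red) track and `c_g` of every
#' second-analog (green) track is removed, the measured ratio becomes
#' `alpha * (1 - c_g) / (1 - c_r)`.
#'
#' @param alpha initial ratio (> 0).
#' @param c_r,c_g cut fractions per analog, each in `[0, 1)`.
#' @return the expected ratio.
#' @export
expected_ratio <- function(alpha, c_r, c_g) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(c_r < 0 | c_r >= 1) || any(c_g < 0 | c_g >= 1))
    stop("cut fractions must be in [0, 1)")
  alpha * (1 - c_g) / (1 - c_r)
}

#' Cut specification for in-silico fiber shortening
#'
#' @param target `"analog1"`, `"analog2"` or `"both"`.
#' @param c_r cut fraction for the first analog (red), in `[0, 1)`.
#' @param c_g cut fraction for the second analog (green), in `[0, 1)`.
#' @return named list of class `cut_spec`.
#' @export
cut_spec <- function(target = c("both", "analog1", "analog2"),
                     c_r = 0, c_g = 0) {
  target <- match.arg(target)
  if (c_r < 0 || c_r >= 1 || c_g < 0 || c_g >= 1)
    stop("cut fractions must be in [0, 1)")
  if (target == "analog1") c_g <- 0
  if (target == "analog2") c_r <- 0
  structure(list(target = target, c_r = c_r, c_g = c_g), class = "cut_spec")
}

# Terminal arc-fraction windows to cut on a ground-truth fiber. Cuts remove
# the terminal end of first/last segments (the end away from the color
# transition), preserving the transition point; middle segments of
# three-segment structures have no terminal end and are skipped.
cut_windows <- function(gt_fiber, spec) {
  segs <- gt_fiber$segments
  b <- segment_bounds(segs$fraction)
  n <- nrow(segs)
  win <- NULL
  for (i in c(1, if (n > 1) n)) {
    lab <- segs$label[i]
    C <- if (lab == ANALOG1) spec$c_r else spec$c_g
    if (C <= 0) next
    w <- C * segs$fraction[i]
    win <- rbind(win, if (i == 1) c(b[1], b[1] + w) else c(b[n + 1] - w,
                                                          b[n + 1]))
  }
  win
}

#' Shorten a fiber in the image by inpainting its cut ends
#'
#' Removes the terminal fraction of the targeted analog's track(s): the cut
#' region (the terminal sub-polyline dilated to the stroke width plus a
#' safety margin) is replaced, per channel and per pixel, by intensities
#' sampled with replacement from an annulus around the fiber stroke, and
#' the ground truth is updated to the shortened geometry.
#'
#' @param img a [fluor_image].
#' @param gt_fiber a `gt_fiber` object.
#' @param spec a [cut_spec()].
#' @param seed integer seed for the inpainting samples.
#' @param min_remaining_px skip the fiber (with a warning) when a cut would
#'   leave a targeted segment shorter than this (default 2).
#' @return list `image` (modified), `gt_fiber` (updated geometry; `NULL`
#'   if the fiber was skipped), `cut_px` (number of inpainted pixels).
#' @export
cut_fiber <- function(img, gt_fiber, spec, seed = 1, min_remaining_px = 2) {
  win <- cut_windows(gt_fiber, spec)
  if (is.null(win)) return(list(image = img, gt_fiber = gt_fiber,
                                cut_px = 0L))
  segs <- gt_fiber$segments
  L <- gt_fiber$arc_length_px
  n <- nrow(segs)
  rem <- segs$fraction * L
  for (i in c(1, if (n > 1) n)) {
    C <- if (segs$label[i] == ANALOG1) spec$c_r else spec$c_g
    rem[i] <- rem[i] * (1 - C)
  }
  if (any(rem < min_remaining_px)) {
    warning("cut would leave a segment below the minimum length; skipped")
    return(list(image = img, gt_fiber = NULL, cut_px = 0L))
  }
  d <- dim(img)
  radius <- gt_fiber$stroke_radius
  # keep window: everything outside the cut windows
  keep <- c(0, 1)
  for (r in seq_len(nrow(win))) {
    if (win[r, 1] <= 1e-12) keep[1] <- max(keep[1], win[r, 2])
    else keep[2] <- min(keep[2], win[r, 1])
  }
  kept_poly <- polyline_section(gt_fiber$polyline, keep[1], keep[2])
  # work on a crop around the fiber; everything below is local coordinates
  pad <- radius + 8
  r0 <- max(1, floor(min(gt_fiber$polyline[, 1]) - pad))
  c0 <- max(1, floor(min(gt_fiber$polyline[, 2]) - pad))
  r1 <- min(d[1], ceiling(max(gt_fiber$polyline[, 1]) + pad))
  c1 <- min(d[2], ceiling(max(gt_fiber$polyline[, 2]) + pad))
  ld <- c(r1 - r0 + 1, c1 - c0 + 1)
  off <- c(r0 - 1, c0 - 1)
  lpoly <- sweep(gt_fiber$polyline, 2, off)
  lkept <- sweep(kept_poly, 2, off)
  # the cut region is the fiber's stroke halo minus the exact stroke of the
  # kept polyline, so the shortened fiber ends in the same rounded cap a
  # genuinely shorter fiber would have
  halo <- rasterize_stroke(lpoly, radius + 2, ld)
  cut_mask <- halo & !rasterize_stroke(lkept, radius, ld)
  fiber_mask <- rasterize_stroke(lpoly, radius, ld)
  ring_pts <- which(fiber_mask, arr.ind = TRUE)
  inner <- stamp_discs(matrix(FALSE, ld[1], ld[2]), ring_pts, radius + 2)
  outer_m <- stamp_discs(matrix(FALSE, ld[1], ld[2]), ring_pts, radius + 6)
  ann_idx <- which(outer_m & !inner, arr.ind = TRUE)
  tgt_idx <- which(cut_mask, arr.ind = TRUE)
  if (nrow(ann_idx) == 0) ann_idx <- which(!fiber_mask, arr.ind = TRUE)
  ann_g <- cbind(ann_idx[, 1] + off[1], ann_idx[, 2] + off[2])
  tgt_g <- cbind(tgt_idx[, 1] + off[1], tgt_idx[, 2] + off[2])
  with_seed(seed, {
    for (k in 1:2) {
      ch <- img$data[, , k]
      ch[tgt_g] <- ch[ann_g][sample.int(nrow(ann_g), nrow(tgt_g),
                                        replace = TRUE)]
      img$data[, , k] <- ch
    }
  })
  target_px <- tgt_g
  # updated ground truth: the trimmed polyline with rescaled fractions
  new_poly <- kept_poly
  new_L <- polyline_length(new_poly)
  new_segs <- data.frame(label = segs$label, fraction = rem / sum(rem))
  out_gt <- structure(list(polyline = new_poly, segments = new_segs,
                           stroke_radius = radius, arc_length_px = new_L),
                      class = "gt_fiber")
  list(image = img, gt_fiber = out_gt, cut_px = nrow(target_px))
}

#' Run a grid of cut experiments through the full pipeline
#'
#' For every `(c_r, c_g)` grid point, all fibers are shortened on a copy of
#' the image, the full analysis pipeline is re-run, detections are matched
#' back to the (updated) ground truth, and the median measured ratio is
#' recorded both over all detected fibers and over the intersection set of
#' ground-truth fibers detected at every grid point.
#'
#' @param img a [fluor_image] (synthetic slide).
#' @param gt ground-truth fiber list for the slide.
#' @param grid data.frame with columns `c_r`, `c_g`.
#' @param config a [pipeline_config()].
#' @param seed integer seed (inpainting).
#' @param alpha construction ratio of the slide (for the expected column);
#'   defaults to the baseline median measured ratio.
#' @return data.frame: `c_r`, `c_g`, `n_detected`, `median_ratio_all`,
#'   `median_ratio_common`, `expected_ratio`.
#' @export
run_cut_experiment <- function(img, gt, grid, config = pipeline_config(),
                               seed = 1, alpha = NULL) {
  d <- dim(img)
  per_level <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- cut_spec("both", c_r = grid$c_r[g], c_g = grid$c_g[g])
    cur <- img
    cur_gt <- vector("list", length(gt))
    if (grid$c_r[g] == 0 && grid$c_g[g] == 0) {
      cur_gt <- gt
    } else {
      for (i in seq_along(gt)) {
        res <- cut_fiber(cur, gt[[i]], spec, seed = seed + 7919L * g + i)
        cur <- res$image
        cur_gt[[i]] <- res$gt_fiber %||% gt[[i]]
      }
    }
    ana <- analyze_fluor_image(cur, config)
    gt_sets <- lapply(cur_gt, function(f) {
      stroke_pixel_set(f$polyline, f$stroke_radius, d)
    })
    pred_sets <- lapply(ana$fibers, fiber_pixel_set, image_dim = d,
                        radius = 3)
    m <- match_detections(pred_sets, gt_sets, iou_threshold = 0.5)
    ratios <- setNames(ana$records$ratio[m$matches$pred],
                       as.character(m$matches$gt))
    per_level[[g]] <- ratios
  }
  common_ids <- Reduce(intersect, lapply(per_level, names))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    r <- per_level[[g]]
    base_alpha <- alpha %||% median(per_level[[1]], na.rm = TRUE)
    data.frame(c_r = grid$c_r[g], c_g = grid$c_g[g],
               n_detected = length(r),
               median_ratio_all = median(r, na.rm = TRUE),
               median_ratio_common = median(r[common_ids], na.rm = TRUE),
               expected_ratio = expected_ratio(base_alpha, grid$c_r[g],
                                               grid$c_g[g]))
  }))
}

#' Degrade an image by Gaussian blur or additive noise
#'
#' @param img a [fluor_image].
#' @param kind `"gaussian_blur"` or `"additive_noise"`.
#' @param level blur sigma in pixels, or noise standard deviation on the
#'   intensity scale; `0` returns the image unchanged.
#' @param seed integer seed (noise only).
#' @return the degraded [fluor_image], clipped to `[0, 255]`.
#' @export
degrade_image <- function(img, kind = c("gaussian_blur", "additive_noise"),
                          level, seed = 1) {
  kind <- match.arg(kind)
  if (level < 0) stop("degradation level must be >= 0")
  if (level == 0) return(img)
  for (k in 1:2) {
    x <- img$data[, , k]
    x <- if (kind == "gaussian_blur") {
      EBImage::gblur(x, level)
    } else {
      with_seed(seed + k,
                x + matrix(rnorm(length(x), 0, level), nrow(x), ncol(x)))
    }
    img$data[, , k] <- clamp(x, 0, 255)
  }
  img
}
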