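# Synthetic two-channel fiber slides with exact ground truth.
#
# Fibers are smooth random polylines (heading random walk with a small
# bounded turn per step, emulating stretched spread fibers), each split into
# 1-3 consecutive single-analog segments. Rendering draws each segment as a
# stroke of fixed radius, max-composites intensities per channel, and then
# applies illumination shading, Gaussian blur, and additive noise to the
# intensities only -- never to the masks.

#' Geometry parameters for the synthetic fiber generator
#'
#' Defaults describe a sparse slide of stretched fibers at 0.26 um/px:
#' lengths 80--150 px (about 21--39 um), nearly straight (heading drift at
#' most 3 degrees per 2-px step), with the segment-structure mix observed in
#' large manual annotation campaigns (roughly 78% two-segment ongoing forks,
#' 13% three-segment structures, 9% single-label tracks) and a lognormal
#' second/first analog ratio with median 1.2.
#'
#' @param length_range fiber arc length range in pixels, `c(min, max)`.
#' @param max_turn_deg maximum absolute heading change per step (degrees).
#' @param step_px arc-length step of the generated polylines (pixels).
#' @param segment_count_probs probabilities of 1, 2, 3 segments.
#' @param ratio_dist ratio distribution: `list(type = "lognormal", meanlog,
#'   sdlog)` or `list(type = "fixed", value)`.
#' @param stroke_radius stroke radius in pixels used for rendering and for
#'   ground-truth masks (the annotation pencil radius).
#' @param min_gap minimum clearance between fiber strokes in pixels; `0`
#'   allows crossings.
#' @param margin minimum distance from the image border, pixels.
#' @return a named list of class `fiber_geometry`.
#' @export
fiber_geometry <- function(length_range = c(80, 150),
                           max_turn_deg = 3,
                           step_px = 2,
                           segment_count_probs = c(0.091, 0.781, 0.129),
                           ratio_dist = list(type = "lognormal",
                                             meanlog = log(1.2),
                                             sdlog = 0.35),
                           stroke_radius = 3,
                           min_gap = 0,
                           margin = 10) {
  if (length(length_range) != 2 || length_range[1] > length_range[2])
    stop("invalid length_range (min > max)")
  if (max_turn_deg < 0 || step_px <= 0 || stroke_radius <= 0 || min_gap < 0)
    stop("geometry parameters must be non-negative (step and radius > 0)")
  if (length(segment_count_probs) != 3 || any(segment_count_probs < 0) ||
      sum(segment_count_probs) <= 0)
    stop("segment_count_probs must be 3 non-negative numbers")
  structure(list(length_range = length_range, max_turn_deg = max_turn_deg,
                 step_px = step_px,
                 segment_count_probs = segment_count_probs /
                   sum(segment_count_probs),
                 ratio_dist = ratio_dist, stroke_radius = stroke_radius,
                 min_gap = min_gap, margin = margin),
            class = "fiber_geometry")
}

sample_ratio <- function(rd) {
  switch(rd$type,
         fixed = rd$value,
         lognormal = rlnorm(1, rd$meanlog, rd$sdlog),
         stop("unknown ratio_dist type: ", rd$type))
}

# Segment table (label, fraction) for a fiber with `k` segments and
# analog2/analog1 length ratio `r`. Two segments follow the labeling
# protocol order (first analog then second); three segments are a divergent
# origin (2-1-2) or convergent fork (1-2-1) with equal probability.
sample_segments <- function(k, r) {
  if (k == 1) {
    return(data.frame(label = sample(c(ANALOG1, ANALOG2), 1), fraction = 1))
  }
  f2 <- r / (1 + r)  # total analog2 fraction
  f1 <- 1 - f2
  if (k == 2) {
    return(data.frame(label = c(ANALOG1, ANALOG2), fraction = c(f1, f2)))
  }
  split <- runif(1, 0.3, 0.7)
  if (runif(1) < 0.5) {  # divergent origin: 2-1-2
    data.frame(label = c(ANALOG2, ANALOG1, ANALOG2),
               fraction = c(f2 * split, f1, f2 * (1 - split)))
  } else {               # convergent fork: 1-2-1
    data.frame(label = c(ANALOG1, ANALOG2, ANALOG1),
               fraction = c(f1 * split, f2, f1 * (1 - split)))
  }
}

# One polyline: heading random walk inside the image box.
sample_polyline <- function(geom, image_size) {
  len <- runif(1, geom$length_range[1], geom$length_range[2])
  n_steps <- max(2, round(len / geom$step_px))
  for (try in 1:50) {
    start <- c(runif(1, geom$margin + 1, image_size[1] - geom$margin),
               runif(1, geom$margin + 1, image_size[2] - geom$margin))
    heading <- runif(1, 0, 2 * pi)
    turns <- runif(n_steps - 1, -1, 1) * geom$max_turn_deg * pi / 180
    headings <- heading + cumsum(c(0, turns))
    # (row, col) steps with x = col, y = -row convention
    pts <- rbind(start,
                 cbind(start[1] + cumsum(-sin(headings) * geom$step_px),
                       start[2] + cumsum(cos(headings) * geom$step_px)))
    if (all(pts[, 1] >= geom$margin + 1) &&
        all(pts[, 1] <= image_size[1] - geom$margin) &&
        all(pts[, 2] >= geom$margin + 1) &&
        all(pts[, 2] <= image_size[2] - geom$margin))
      return(pts)
  }
  NULL
}

#' Generate a set of ground-truth fibers
#'
#' Samples `n_fibers` fibers with smooth polyline geometry and 1--3
#' single-analog segments. With `geom$min_gap > 0`, fibers are placed by
#' rejection sampling so that strokes keep at least that clearance (no
#' crossings); with `min_gap = 0` fibers may cross freely.
#'
#' @param n_fibers number of fibers (>= 0).
#' @param image_size `c(rows, cols)` of the target canvas.
#' @param geom a [fiber_geometry()].
#' @param seed integer; fixes all randomness.
#' @return list of `gt_fiber` objects, each with elements `polyline`
#'   (n x 2 matrix of (row, col) points), `segments` (data.frame `label`,
#'   `fraction`), `stroke_radius`, and `arc_length_px`.
#' @export
generate_fiber_set <- function(n_fibers, image_size = c(512, 512),
                               geom = fiber_geometry(), seed = 1) {
  stopifnot(n_fibers >= 0)
  if (!inherits(geom, "fiber_geometry")) geom <- do.call(fiber_geometry, geom)
  with_seed(seed, {
    fibers <- vector("list", n_fibers)
    occupancy <- if (geom$min_gap > 0)
      matrix(FALSE, image_size[1], image_size[2])
    placed <- 0
    attempts <- 0
    max_attempts <- max(200, n_fibers * 100)
    while (placed < n_fibers && attempts < max_attempts) {
      attempts <- attempts + 1
      pts <- sample_polyline(geom, image_size)
      if (is.null(pts)) next
      if (geom$min_gap > 0) {
        ipts <- cbind(clamp(round(pts[, 1]), 1, image_size[1]),
                      clamp(round(pts[, 2]), 1, image_size[2]))
        if (any(occupancy[ipts])) next
        occupancy <- stamp_discs(occupancy, ipts,
                                 2 * geom$stroke_radius + geom$min_gap)
      }
      placed <- placed + 1
      k <- sample.int(3, 1, prob = geom$segment_count_probs)
      r <- sample_ratio(geom$ratio_dist)
      fibers[[placed]] <- structure(
        list(polyline = unname(pts),
             segments = sample_segments(k, r),
             stroke_radius = geom$stroke_radius,
             arc_length_px = polyline_length(pts)),
        class = "gt_fiber")
    }
    if (placed < n_fibers)
      warning(sprintf("placed only %d of %d fibers (crowded canvas)",
                      placed, n_fibers))
    fibers[seq_len(placed)]
  })
}

#' Rendering parameters for synthetic slides
#'
#' @param image_size `c(rows, cols)`, both > 0.
#' @param background_level constant background intensity (0--255 scale).
#' @param illumination_gradient relative amplitude of a smooth linear shading
#'   field (`0` disables it).
#' @param psf_sigma Gaussian point-spread sigma in pixels (`0` = no blur).
#' @param noise_sigma additive Gaussian noise standard deviation (`0` = none).
#' @param fiber_intensity length-2 per-channel stroke intensity.
#' @param pixel_size micrometres per pixel stamped on the output image.
#' @param seed integer; fixes noise and shading direction.
#' @return named list of class `render_params`.
#' @export
render_params <- function(image_size = c(512, 512), background_level = 10,
                          illumination_gradient = 0.2, psf_sigma = 1,
                          noise_sigma = 5, fiber_intensity = c(180, 180),
                          pixel_size = 0.26, seed = 1) {
  if (any(image_size <= 0)) stop("zero-size image")
  vals <- c(background_level, illumination_gradient, psf_sigma, noise_sigma,
            fiber_intensity)
  if (any(vals < 0)) stop("render parameters must be non-negative")
  structure(list(image_size = image_size,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 psf_sigma = psf_sigma, noise_sigma = noise_sigma,
                 fiber_intensity = fiber_intensity, pixel_size = pixel_size,
                 seed = seed),
            class = "render_params")
}

# Pixels covered by the stroke of radius `radius` swept along `pts`:
# every pixel centre within `radius` of the polyline. Exact point-to-segment
# distances, vectorized per segment over its bounding box.
rasterize_stroke <- function(pts, radius, image_size) {
  hits <- matrix(FALSE, image_size[1], image_size[2])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    r0 <- max(1, floor(min(a[1], b[1]) - radius))
    r1 <- min(image_size[1], ceiling(max(a[1], b[1]) + radius))
    c0 <- max(1, floor(min(a[2], b[2]) - radius))
    c1 <- min(image_size[2], ceiling(max(a[2], b[2]) + radius))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    pr <- rep(rr, times = length(cc)); pc <- rep(cc, each = length(rr))
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) {
      d2 <- (pr - a[1])^2 + (pc - a[2])^2
    } else {
      t <- clamp(((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2, 0, 1)
      d2 <- (pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2
    }
    sel <- d2 <= radius^2 + 1e-9
    if (any(sel)) hits[cbind(pr[sel], pc[sel])] <- TRUE
  }
  hits
}

# Stroke pixels of a whole fiber together with per-pixel analog labels.
# Every pixel centre within `radius` of the polyline is a stroke pixel; its
# label is that of the segment containing the arc position of its nearest
# point on the centerline, so segment boundaries are perpendicular cuts at
# the exact transition. Pixels whose arc position falls within half a pixel
# of an interior boundary are ambiguous transition pixels and are assigned
# to the second analog, mirroring the annotation convention.
rasterize_fiber_labels <- function(polyline, bounds, labels, radius,
                                   image_size) {
  r0 <- max(1, floor(min(polyline[, 1]) - radius - 1))
  r1 <- min(image_size[1], ceiling(max(polyline[, 1]) + radius + 1))
  c0 <- max(1, floor(min(polyline[, 2]) - radius - 1))
  c1 <- min(image_size[2], ceiling(max(polyline[, 2]) + radius + 1))
  if (r0 > r1 || c0 > c1)
    return(list(px = matrix(integer(0), 0, 2), label = integer(0)))
  nr <- r1 - r0 + 1; nc <- c1 - c0 + 1
  pr <- rep(r0:r1, times = nc); pc <- rep(c0:c1, each = nr)
  best_d2 <- rep(Inf, nr * nc)
  best_arc <- rep(0, nr * nc)
  s <- c(0, cumsum(sqrt(rowSums(diff(polyline)^2))))
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) next
    t <- clamp(((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2, 0, 1)
    d2 <- (pr - (a[1] + t * ab[1]))^2 + (pc - (a[2] + t * ab[2]))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- s[i] + t[upd] * sqrt(len2)
  }
  sel <- best_d2 <= radius^2 + 1e-9
  if (!any(sel))
    return(list(px = matrix(integer(0), 0, 2), label = integer(0)))
  arc <- best_arc[sel]
  L <- s[length(s)]
  cuts <- bounds * L
  seg_idx <- findInterval(arc, cuts, rightmost.closed = TRUE,
                          all.inside = TRUE)
  lab <- labels[seg_idx]
  interior <- cuts[-c(1, length(cuts))]
  if (length(interior) > 0) {
    near <- vapply(seq_along(arc), function(k) {
      any(abs(arc[k] - interior) <= 0.5)
    }, logical(1))
    lab[near] <- ANALOG2
  }
  list(px = cbind(pr[sel], pc[sel]), label = lab)
}

#' Render ground-truth fibers into an image, class mask and instance map
#'
#' Each segment is drawn as a stroke of the fiber's `stroke_radius` in its
#' analog's channel. Within a fiber, pixels covered by segments of both
#' analogs (the color transition) are assigned to the second analog,
#' matching the annotation convention for ambiguous transition pixels.
#' Across fibers, intensities are max-composited per channel while the class
#' mask and instance map follow draw order (the later fiber wins).
#' Illumination shading, blur and noise degrade the intensities only.
#'
#' @param gt list of `gt_fiber` objects from [generate_fiber_set()].
#' @param params a [render_params()].
#' @return list with `image` ([fluor_image]), `mask` (integer matrix, 0 =
#'   background, 1 = analog 1, 2 = analog 2), `instance` (integer matrix of
#'   fiber ids, 0 = background), `clipped` (logical, any polyline outside
#'   the canvas).
#' @export
render_fibers <- function(gt, params = render_params()) {
  sz <- params$image_size
  if (any(sz <= 0)) stop("zero-size image")
  ch <- list(matrix(0, sz[1], sz[2]), matrix(0, sz[1], sz[2]))
  mask <- matrix(0L, sz[1], sz[2])
  instance <- matrix(0L, sz[1], sz[2])
  clipped <- FALSE
  for (fid in seq_along(gt)) {
    f <- gt[[fid]]
    if (any(f$polyline < 1) || any(f$polyline[, 1] > sz[1]) ||
        any(f$polyline[, 2] > sz[2])) clipped <- TRUE
    ras <- rasterize_fiber_labels(f$polyline,
                                  segment_bounds(f$segments$fraction),
                                  f$segments$label, f$stroke_radius, sz)
    if (nrow(ras$px) == 0) next
    mask[ras$px] <- ras$label
    instance[ras$px] <- fid
    for (k in 1:2) {
      sel <- ras$label == k
      if (any(sel)) {
        idx <- ras$px[sel, , drop = FALSE]
        ch[[k]][idx] <- pmax(ch[[k]][idx], params$fiber_intensity[k])
      }
    }
  }
  with_seed(params$seed, {
    shade <- matrix(1, sz[1], sz[2])
    if (params$illumination_gradient > 0) {
      theta <- runif(1, 0, 2 * pi)
      ramp <- outer(seq(-0.5, 0.5, length.out = sz[1]) * cos(theta),
                    seq(-0.5, 0.5, length.out = sz[2]) * sin(theta), "+")
      ramp <- ramp - min(ramp)
      if (max(ramp) > 0) ramp <- ramp / max(ramp)
      shade <- 1 - params$illumination_gradient * ramp
    }
    for (k in 1:2) {
      x <- (params$background_level + ch[[k]]) * shade
      if (params$psf_sigma > 0) x <- EBImage::gblur(x, params$psf_sigma)
      if (params$noise_sigma > 0)
        x <- x + matrix(rnorm(length(x), 0, params$noise_sigma),
                        nrow(x), ncol(x))
      ch[[k]] <- clamp(x, 0, 255)
    }
  })
  img <- fluor_image(ch[[1]], ch[[2]], pixel_size = params$pixel_size)
  list(image = img, mask = mask, instance = instance, clipped = clipped)
}

# Cumulative segment boundaries 0 = f0 < f1 < ... <= 1 from fractions.
segment_bounds <- function(fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("segment fractions must sum to 1")
  c(0, cumsum(fractions))
}

#' Ground-truth table for a fiber set
#'
#' @param gt list of `gt_fiber`s.
#' @param pixel_size micrometres per pixel.
#' @return data.frame with one row per segment: `fiber_id`, `segment`,
#'   `label`, `length_px`, `length_um`.
#' @export
ground_truth_table <- function(gt, pixel_size = 0.26) {
  do.call(rbind, lapply(seq_along(gt), function(i) {
    f <- gt[[i]]
    lp <- f$segments$fraction * f$arc_length_px
    data.frame(fiber_id = i, segment = seq_len(nrow(f$segments)),
               label = f$segments$label, length_px = lp,
               length_um = lp * pixel_size)
  }))
}

#' Write a synthetic slide (image, masks, ground truth) to disk
#'
#' @param rendered output of [render_fibers()].
#' @param gt the fiber set that was rendered.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the vector of written paths.
#' @export
write_synthetic_slide <- function(rendered, gt, out_dir, prefix = "slide") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(out_dir, paste0(prefix, c(".tif", "_mask.png", "_gt.csv",
                                           "_polylines.json")))
  write_fluor_image(rendered$image, p[1])
  write_seg_mask(rendered$mask, p[2])
  write.csv(ground_truth_table(gt, rendered$image$pixel_size), p[3],
            row.names = FALSE)
  jsonlite::write_json(
    lapply(gt, function(f) list(polyline = unname(f$polyline),
                                label = f$segments$label,
                                fraction = f$segments$fraction,
                                stroke_radius = f$stroke_radius)),
    p[4], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
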