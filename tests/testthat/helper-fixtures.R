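# Shared fixtures and independent oracles. Everything is generated in code;
# no data files.

# A straight ground-truth fiber from p0 to p1 with given segment fractions.
straight_gt_fiber <- function(p0, p1, fractions = c(0.5, 0.5),
                              labels = c(1L, 2L), radius = 3) {
  pts <- rbind(p0, p1)
  structure(list(polyline = pts,
                 segments = data.frame(label = as.integer(labels),
                                       fraction = fractions),
                 stroke_radius = radius,
                 arc_length_px = sqrt(sum((p1 - p0)^2))),
            class = "gt_fiber")
}

# Clean (noise/blur/shading-free) rendering of a fiber set.
clean_render <- function(gt, size, seed = 1) {
  render_fibers(gt, render_params(image_size = size, background_level = 8,
                                  illumination_gradient = 0, psf_sigma = 0,
                                  noise_sigma = 0, seed = seed))
}

# Clean non-crossing two-segment slide used by several suites.
clean_slide <- function(n = 25, size = c(700, 700), seed = 1,
                        ratio = list(type = "lognormal",
                                     meanlog = log(1.2), sdlog = 0.35)) {
  geom <- fiber_geometry(min_gap = 8, segment_count_probs = c(0, 1, 0),
                         ratio_dist = ratio)
  gt <- generate_fiber_set(n, size, geom, seed = seed)
  list(gt = gt, rendered = clean_render(gt, size, seed))
}

# Two straight bicolor fibers crossing at `angle_deg`, with independent
# crossing and transition positions.
crossing_pair <- function(seed, size = c(300, 300)) {
  set.seed(seed)
  ang <- runif(1, 45, 90) * pi / 180
  ctr <- size / 2
  L <- runif(2, 80, 130)
  th1 <- runif(1, 0, pi)
  th <- c(th1, th1 + ang)
  frx <- runif(2, 0.30, 0.70)
  frt <- runif(2, 0.35, 0.65)
  gt <- lapply(1:2, function(i) {
    u <- c(-sin(th[i]), cos(th[i]))
    straight_gt_fiber(ctr - u * L[i] * frx[i], ctr + u * L[i] * (1 - frx[i]),
                      fractions = c(frt[i], 1 - frt[i]))
  })
  list(gt = gt, angle_deg = ang * 180 / pi)
}

# ---- independent oracles ---------------------------------------------------

# Brute-force disc-swept rasterizer: scalar loop over every pixel and every
# polyline segment.
brute_rasterize <- function(pts, radius, size) {
  out <- matrix(FALSE, size[1], size[2])
  for (r in seq_len(size[1])) for (cc in seq_len(size[2])) {
    dmin <- Inf
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 < 1e-12) 0 else
        min(1, max(0, sum((c(r, cc) - a) * ab) / len2))
      p <- a + t * ab
      dmin <- min(dmin, sqrt(sum((c(r, cc) - p)^2)))
    }
    if (dmin <= radius + 1e-9) out[r, cc] <- TRUE
  }
  out
}

# Brute-force single-linkage agglomeration: merge any two clusters whose
# closest members are within h, until no such pair remains.
brute_single_linkage <- function(pts, h) {
  clusters <- as.list(seq_len(nrow(pts)))
  repeat {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dmin <- min(vapply(clusters[[i]], function(a) {
          min(sqrt((pts[clusters[[j]], 1] - pts[a, 1])^2 +
                     (pts[clusters[[j]], 2] - pts[a, 2])^2))
        }, numeric(1)))
        if (dmin <= h) {
          clusters[[i]] <- c(clusters[[i]], clusters[[j]])
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters
}

# Cliff's delta by direct pair enumeration.
brute_cliffs_delta <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Hand simulation of greedy IoU matching: sort candidate pairs by
# decreasing IoU (ties by pred then gt), accept while both sides unused.
brute_greedy_match <- function(pred, gt, thr) {
  rows <- NULL
  for (i in seq_along(pred)) for (j in seq_along(gt)) {
    inter <- length(intersect(pred[[i]], gt[[j]]))
    u <- length(pred[[i]]) + length(gt[[j]]) - inter
    v <- if (u == 0) 0 else inter / u
    if (v > thr) rows <- rbind(rows, c(i, j, v))
  }
  if (is.null(rows)) return(data.frame(pred = integer(0), gt = integer(0)))
  rows <- rows[order(-rows[, 3], rows[, 1], rows[, 2]), , drop = FALSE]
  up <- logical(length(pred)); ug <- logical(length(gt))
  keep <- NULL
  for (r in seq_len(nrow(rows))) {
    i <- rows[r, 1]; j <- rows[r, 2]
    if (up[i] || ug[j]) next
    up[i] <- TRUE; ug[j] <- TRUE
    keep <- rbind(keep, rows[r, 1:2])
  }
  data.frame(pred = keep[, 1], gt = keep[, 2])
}

# Measured-vs-planted segment comparison for a clean slide analysis.
segment_errors <- function(gt, fibers, image_dim) {
  gt_sets <- lapply(gt, function(f)
    fibertrace:::stroke_pixel_set(f$polyline, f$stroke_radius, image_dim))
  pred_sets <- lapply(fibers, fiber_pixel_set, image_dim = image_dim,
                      radius = 3)
  m <- match_detections(pred_sets, gt_sets)
  errs <- c()
  for (k in seq_len(nrow(m$matches))) {
    g <- gt[[m$matches$gt[k]]]
    gtl <- g$segments$fraction * g$arc_length_px
    mm <- measure_fiber(fibers[[m$matches$pred[k]]], 1)
    ml <- mm$segments$length_um
    if (length(ml) != length(gtl)) next
    if (mm$segments$label[1] != g$segments$label[1]) ml <- rev(ml)
    errs <- c(errs, abs(ml - gtl) / gtl)
  }
  list(match = m, errors = errs)
}
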