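# Skeletonization and junction geometry: class masks are reduced to 1-px
# centerlines, branch points are found with neighborhood templates, nearby
# junction pixels are merged by single-linkage clustering, and circular
# regions around each junction are erased to split the skeleton into
# branches.

#' Skeletonize a class mask
#'
#' Thins the union foreground (both analog classes) to 1-px-wide centerlines
#' with an endpoint-preserving morphological thinning (Guo-Hall, followed by
#' a staircase-corner cleanup; pixels with a single neighbour are never
#' removed, so line ends are kept).
#' Thinning decisions are purely local, so thinning the whole mask at once
#' is identical to thinning each connected component individually. Each
#' skeleton pixel inherits the analog label of the mask at its location, and
#' the fiber stroke width is estimated as twice the median distance-map
#' value over skeleton pixels.
#'
#' @param mask integer matrix with classes `{0, 1, 2}`.
#' @return object of class `skeleton_graph`: list with `skeleton` (logical
#'   matrix), `labels` (integer matrix, 0 off the skeleton), `width`
#'   (estimated stroke width, px) and `dim`.
#' @export
skeletonize <- function(mask) {
  if (!all(mask %in% 0:2)) stop("mask classes must be in {0, 1, 2}")
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  skel <- thin_guo_hall(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[skel] <- mask[skel]
  width <- 0
  if (any(skel)) {
    dm <- EBImage::distmap(matrix(as.numeric(mask > 0), nrow(mask)))
    width <- 2 * median(dm[skel])
  }
  structure(list(skeleton = skel, labels = labels, width = width,
                 dim = dim(mask)),
            class = "skeleton_graph")
}

#' Detect skeleton branch points
#'
#' Tests every skeleton pixel's 3x3 neighbourhood against branch-point
#' templates: a pixel is a junction candidate when it has at least three
#' skeleton neighbours falling in at least three distinct runs around the
#' neighbourhood ring (crossing number >= 3).
#'
#' @param sk a [skeletonize()] result.
#' @return n x 2 integer matrix of junction pixel (row, col) coordinates,
#'   ordered lexicographically.
#' @export
detect_junctions <- function(sk) {
  nct <- neighbor_counts(sk$skeleton)
  crs <- crossing_numbers(sk$skeleton)
  idx <- which(sk$skeleton & nct >= 3 & crs >= 3, arr.ind = TRUE)
  colnames(idx) <- NULL
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Merge nearby junction pixels by single-linkage clustering
#'
#' Junction pixels whose single-linkage chain distance is at most
#' `threshold` are consolidated into one junction; the junction centre is
#' the cluster centroid rounded to the nearest pixel.
#'
#' @param pixels n x 2 matrix of junction pixel coordinates.
#' @param threshold linkage distance threshold in pixels (default 10).
#' @return m x 2 integer matrix of junction centres (lexicographic order).
#' @export
cluster_junctions <- function(pixels, threshold = 10) {
  if (is.null(pixels) || nrow(pixels) == 0)
    return(matrix(integer(0), 0, 2))
  if (nrow(pixels) == 1) return(matrix(as.integer(round(pixels)), 1, 2))
  cl <- cutree(hclust(dist(pixels), method = "single"), h = threshold)
  centers <- t(vapply(split(seq_len(nrow(pixels)), cl), function(i) {
    round(colMeans(pixels[i, , drop = FALSE]))
  }, numeric(2)))
  centers <- matrix(as.integer(centers), ncol = 2)
  centers[order(centers[, 1], centers[, 2]), , drop = FALSE]
}

# Order the pixels of a thin 8-connected component into a path. `px` is an
# n x 2 coordinate matrix. Returns an index vector into px, or NULL for
# degenerate clumps that cannot be walked.
order_component_path <- function(px) {
  n <- nrow(px)
  if (n == 1) return(1L)
  # adjacency by coordinate hashing
  key <- px[, 1] * 1e6 + px[, 2]
  off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  nb <- lapply(seq_len(n), function(i) {
    k <- (px[i, 1] + off[, 1]) * 1e6 + (px[i, 2] + off[, 2])
    which(key %in% k)
  })
  deg <- lengths(nb)
  lex <- order(px[, 1], px[, 2])
  ends <- lex[deg[lex] <= 1]
  start <- if (length(ends) > 0) ends[1] else lex[1]  # loop: break at lex min
  is4 <- function(i, j) sum(abs(px[i, ] - px[j, ])) == 1
  walk <- function(start) {
    visited <- logical(n)
    path <- integer(n)
    path[1] <- start; visited[start] <- TRUE
    m <- 1
    repeat {
      cand <- nb[[path[m]]]
      cand <- cand[!visited[cand]]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        four <- cand[vapply(cand, is4, logical(1), i = path[m])]
        pool <- if (length(four) > 0) four else cand
        pool <- pool[order(px[pool, 1], px[pool, 2])]
        cand <- pool[1]
      }
      m <- m + 1
      path[m] <- cand
      visited[cand] <- TRUE
    }
    path[seq_len(m)]
  }
  p <- walk(start)
  if (length(p) < 0.8 * n && length(ends) > 1) {
    alt <- lapply(ends, walk)
    p <- alt[[which.max(lengths(alt))]]
  }
  p
}

#' Direction angle at a branch endpoint
#'
#' The angle of the vector from the point `trace_px` path-pixels inward
#' (or the far end for shorter branches) to the endpoint, in `(-pi, pi]`,
#' with `x = col`, `y = -row` so that "right" is 0 and "up" (decreasing
#' row) is `pi/2`. The direction points outward, i.e. away from the branch
#' body and towards whatever the endpoint abuts.
#'
#' @param branch a branch object (list with `path`).
#' @param end `1` (path start) or `2` (path end).
#' @param trace_px how far along the skeleton to trace (default 15).
#' @return angle in radians.
#' @export
endpoint_direction <- function(branch, end, trace_px = 15) {
  path <- branch$path
  n <- nrow(path)
  if (n < 2) stop("branch must have at least 2 pixels")
  if (end == 2) {
    point_angle(path[max(1, n - trace_px), ], path[n, ])
  } else {
    point_angle(path[min(n, 1 + trace_px), ], path[1, ])
  }
}

# Majority label over the `k` path pixels nearest the given end; a short
# window keeps the label local so a color transition sitting just inside
# the branch does not flip the end label. Ties resolve to the second
# analog (the annotation transition convention).
end_label <- function(labels, end, k = 5) {
  n <- length(labels)
  sel <- if (end == 1) labels[seq_len(min(k, n))] else
    labels[seq(max(1, n - k + 1), n)]
  sel <- sel[sel > 0]
  if (length(sel) == 0) return(ANALOG2)
  tab <- tabulate(sel, 2)
  if (tab[2] >= tab[1]) ANALOG2 else ANALOG1
}

# Build a branch object from an ordered pixel path and the label raster.
make_branch <- function(id, path, label_raster, trace_px = 15) {
  labels <- label_raster[path]
  n <- nrow(path)
  tab <- tabulate(labels[labels > 0], 2)
  br <- list(id = id, path = path, labels = labels,
             length_px = naive_path_length(path),
             dominant_label = if (tab[2] >= tab[1]) ANALOG2 else ANALOG1)
  br$endpoints <- lapply(1:2, function(e) {
    list(pos = path[if (e == 1) 1 else n, ],
         angle = endpoint_direction(br, e, trace_px),
         label = end_label(labels, e))
  })
  br
}

# Naive chain length: 1 per orthogonal step, sqrt(2) per diagonal step.
naive_path_length <- function(path) {
  if (nrow(path) < 2) return(0)
  st <- abs(diff(path))
  sum(ifelse(rowSums(st) == 2, sqrt(2), 1))
}

# Consolidate junction centres whose erase discs would overlap: shallow
# crossings spread their branch pixels over more than the clustering
# threshold, and erasing two half-overlapping discs strands fragments and
# splits the endpoint set. Iterates single-linkage merging at the erase
# radius.
merge_close_junctions <- function(centers, radius) {
  while (nrow(centers) > 1) {
    d <- as.matrix(dist(centers))
    diag(d) <- Inf
    if (min(d) > radius) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    merged <- round(colMeans(centers[ij, , drop = FALSE]))
    centers <- rbind(centers[-ij, , drop = FALSE], merged)
  }
  centers <- matrix(as.integer(centers), ncol = 2)
  centers[order(centers[, 1], centers[, 2]), , drop = FALSE]
}

#' Erase junction regions and split the skeleton into branches
#'
#' Removes a circular disc of radius `radius_factor * width` around every
#' junction centre, splits the remaining skeleton into 8-connected
#' components, orders each into a pixel path, and discards branches shorter
#' than `min_branch_px` pixels.
#'
#' @param sk a [skeletonize()] result.
#' @param junctions m x 2 matrix of junction centres
#'   (from [cluster_junctions()]).
#' @param radius_factor erasure radius as a multiple of the estimated fiber
#'   width (default 1.5).
#' @param min_branch_px minimum branch size in pixels (default 5).
#' @param trace_px direction-estimation trace length (default 15).
#' @return list of branch objects (`id`, `path`, `labels`, `length_px`,
#'   `dominant_label`, `endpoints`).
#' @export
erase_and_split <- function(sk, junctions, radius_factor = 1.5,
                            min_branch_px = 5, trace_px = 15) {
  skel <- sk$skeleton
  radius <- max(2, radius_factor * sk$width)
  if (nrow(junctions) > 0)
    skel <- stamp_discs(skel, junctions, radius, value = FALSE)
  # remove residual branch pixels so every component is a simple path
  for (i in 1:5) {
    resid <- which(skel & neighbor_counts(skel) >= 3 &
                     crossing_numbers(skel) >= 3)
    if (length(resid) == 0) break
    skel[resid] <- FALSE
  }
  lab <- label_components(skel, 8L)
  ncomp <- max(lab)
  if (ncomp == 0) return(list())
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  branches <- list()
  for (ci in seq_len(ncomp)) {
    px <- idx[comp == ci, , drop = FALSE]
    if (nrow(px) < min_branch_px) next
    ord <- order_component_path(px)
    if (length(ord) < min_branch_px) next
    path <- px[ord, , drop = FALSE]
    colnames(path) <- NULL
    branches[[length(branches) + 1]] <-
      make_branch(length(branches) + 1L, path, sk$labels, trace_px)
  }
  branches
}
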