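# Endpoint matching across junctions, reconnection, fiber grouping and
# final cleaning.

#' Match branch endpoints at a junction
#'
#' Pairs branch endpoints across an erased junction with a weighted cost
#' combining spatial proximity (endpoint distance normalized by the maximum
#' matching distance), angular compatibility (favoring outward directions
#' about 180 degrees apart, i.e. collinear continuation through the
#' junction), and color consistency (penalizing pairs whose endpoint-local
#' analog labels differ). Two endpoints are paired directly; with three, the
#' minimum-cost pair is kept and the leftover tip is flagged for
#' reconnection to the junction centre; with four, all three perfect
#' matchings are enumerated and the minimum-total-cost one is chosen. Five
#' or more endpoints are matched greedily by ascending pairwise cost (with a
#' warning). Endpoints farther than `max_dist` from the junction centre must
#' be excluded by the caller; the two ends of one branch are never paired
#' with each other.
#'
#' @param center junction centre `(row, col)`.
#' @param endpoints data.frame with columns `branch`, `end`, `row`, `col`,
#'   `angle`, `label` (one row per candidate endpoint).
#' @param max_dist maximum matching distance (pixels), used to normalize
#'   the distance cost.
#' @param weights length-3 numeric: distance, angle and color weights.
#' @return list with `pairs` (k x 2 matrix of endpoint row indices) and
#'   `tips` (indices of leftover endpoints to reconnect to the centre).
#' @export
match_endpoints <- function(center, endpoints, max_dist,
                            weights = c(0.15, 0.65, 0.2)) {
  n <- nrow(endpoints)
  empty <- list(pairs = matrix(integer(0), 0, 2), tips = integer(0))
  if (n < 2) {
    empty$tips <- seq_len(n)
    return(empty)
  }
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (endpoints$branch[i] == endpoints$branch[j]) next
    d <- sqrt((endpoints$row[i] - endpoints$row[j])^2 +
                (endpoints$col[i] - endpoints$col[j])^2)
    ang <- abs(pi - abs(wrap_angle(endpoints$angle[i] -
                                     endpoints$angle[j]))) / pi
    col_pen <- as.numeric(endpoints$label[i] != endpoints$label[j])
    cost[i, j] <- cost[j, i] <-
      weights[1] * d / max_dist + weights[2] * ang + weights[3] * col_pen
  }
  if (n == 2) {
    if (!is.finite(cost[1, 2])) return(list(pairs = empty$pairs, tips = 1:2))
    return(list(pairs = matrix(1:2, 1, 2), tips = integer(0)))
  }
  if (n == 3) {
    pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
    costs <- cost[pairs]
    if (all(!is.finite(costs))) return(list(pairs = empty$pairs, tips = 1:3))
    best <- pairs[which.min(costs), ]
    return(list(pairs = matrix(best, 1, 2), tips = setdiff(1:3, best)))
  }
  if (n == 4) {
    matchings <- list(rbind(c(1, 2), c(3, 4)),
                      rbind(c(1, 3), c(2, 4)),
                      rbind(c(1, 4), c(2, 3)))
    totals <- vapply(matchings, function(m) sum(cost[m]), numeric(1))
    if (all(!is.finite(totals)))
      return(list(pairs = empty$pairs, tips = 1:4))
    return(list(pairs = matchings[[which.min(totals)]], tips = integer(0)))
  }
  warning(sprintf("junction at (%d, %d) with %d endpoints; greedy matching",
                  center[1], center[2], n))
  used <- logical(n)
  pairs <- matrix(integer(0), 0, 2)
  ij <- which(upper.tri(cost), arr.ind = TRUE)
  ij <- ij[order(cost[ij]), , drop = FALSE]
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    if (used[i] || used[j] || !is.finite(cost[i, j])) next
    pairs <- rbind(pairs, c(i, j))
    used[i] <- used[j] <- TRUE
  }
  list(pairs = pairs, tips = which(!used))
}

# Assign every branch endpoint to its nearest junction centre (within
# max_dist) and run matching junction by junction, in lexicographic centre
# order. Each endpoint participates in at most one junction.
match_all_junctions <- function(branches, junctions, width,
                                max_dist_factor = 3,
                                weights = c(0.15, 0.65, 0.2)) {
  if (length(branches) == 0 || nrow(junctions) == 0) return(list())
  eps <- do.call(rbind, lapply(branches, function(b) {
    data.frame(branch = b$id, end = 1:2,
               row = c(b$endpoints[[1]]$pos[1], b$endpoints[[2]]$pos[1]),
               col = c(b$endpoints[[1]]$pos[2], b$endpoints[[2]]$pos[2]),
               angle = c(b$endpoints[[1]]$angle, b$endpoints[[2]]$angle),
               label = c(b$endpoints[[1]]$label, b$endpoints[[2]]$label))
  }))
  max_dist <- max_dist_factor * max(width, 2)
  dmat <- outer(eps$row, junctions[, 1], "-")^2 +
    outer(eps$col, junctions[, 2], "-")^2
  nearest <- apply(dmat, 1, which.min)
  nd <- sqrt(dmat[cbind(seq_len(nrow(eps)), nearest)])
  assigned <- ifelse(nd <= max_dist, nearest, NA)
  out <- list()
  for (ji in seq_len(nrow(junctions))) {
    sel <- which(!is.na(assigned) & assigned == ji)
    if (length(sel) == 0) next
    m <- match_endpoints(junctions[ji, ], eps[sel, , drop = FALSE],
                         max_dist, weights)
    out[[length(out) + 1]] <- list(
      center = junctions[ji, ],
      pairs = matrix(sel[m$pairs], ncol = 2),
      tips = sel[m$tips],
      endpoints = eps[sel, , drop = FALSE])
  }
  attr(out, "endpoint_table") <- eps
  out
}

#' Reconnect matched branches and group them into fibers
#'
#' Draws straight reconnection paths between matched endpoints; the
#' reconnection carries the second-analog label when the two endpoint-local
#' labels differ (a color transition crossing the junction), otherwise the
#' shared label. Unmatched T-junction tips are extended to the junction
#' centre with their own label; this restores erased length but adds no
#' adjacency, so the crossing fiber stays separate. Fibers are the
#' connected components of the branch adjacency graph built from the
#' pairings; components that form a cycle are dropped, and reconstructed
#' fibers carrying a single analog label or shorter than `min_total_px`
#' are discarded.
#'
#' @param branches branch list from [erase_and_split()].
#' @param junction_matches output of the per-junction matching (see
#'   [match_endpoints()]); a list with elements `pairs`, `tips`, `center`,
#'   `endpoints`.
#' @param min_total_px minimum reconstructed fiber length in pixels
#'   (default 15).
#' @param min_segment_px label runs shorter than this are absorbed into
#'   their larger neighbour run before segments are reported (default 5).
#' @return list of fiber objects: `path`, `labels`, `segments`
#'   (data.frame `label`, `n_px`, `length_px`), `total_px`.
#' @export
reconnect_and_group <- function(branches, junction_matches,
                                min_total_px = 15, min_segment_px = 5) {
  if (length(branches) == 0) return(list())
  # connection slots: conn[[branch]][[end]] = list(branch, end, path, labels)
  conn <- lapply(branches, function(b) list(NULL, NULL))
  for (jm in junction_matches) {
    eps <- attr(junction_matches, "endpoint_table")
    for (r in seq_len(nrow(jm$pairs))) {
      i <- jm$pairs[r, 1]; j <- jm$pairs[r, 2]
      bi <- eps$branch[i]; ei <- eps$end[i]
      bj <- eps$branch[j]; ej <- eps$end[j]
      if (!is.null(conn[[bi]][[ei]]) || !is.null(conn[[bj]][[ej]])) next
      seg <- bresenham(c(eps$row[i], eps$col[i]), c(eps$row[j], eps$col[j]))
      lab <- if (eps$label[i] != eps$label[j]) ANALOG2 else eps$label[i]
      conn[[bi]][[ei]] <- list(branch = bj, end = ej, path = seg, label = lab)
      conn[[bj]][[ej]] <- list(branch = bi, end = ei,
                               path = seg[rev(seq_len(nrow(seg))), ,
                                          drop = FALSE],
                               label = lab)
    }
    for (t in jm$tips) {
      bt <- eps$branch[t]; et <- eps$end[t]
      seg <- bresenham(c(eps$row[t], eps$col[t]), jm$center)
      if (nrow(seg) < 2) next
      ext <- seg[-1, , drop = FALSE]
      b <- branches[[bt]]
      if (et == 1) {
        b$path <- rbind(ext[rev(seq_len(nrow(ext))), , drop = FALSE], b$path)
        b$labels <- c(rep(eps$label[t], nrow(ext)), b$labels)
      } else {
        b$path <- rbind(b$path, ext)
        b$labels <- c(b$labels, rep(eps$label[t], nrow(ext)))
      }
      branches[[bt]] <- b
    }
  }
  # group branches into fibers (connected components over pairings)
  n <- length(branches)
  visited <- logical(n)
  fibers <- list()
  for (b0 in seq_len(n)) {
    if (visited[b0]) next
    # collect component
    comp <- integer(0)
    queue <- b0
    while (length(queue) > 0) {
      b <- queue[1]; queue <- queue[-1]
      if (visited[b]) next
      visited[b] <- TRUE
      comp <- c(comp, b)
      for (e in 1:2)
        if (!is.null(conn[[b]][[e]])) queue <- c(queue, conn[[b]][[e]]$branch)
    }
    # find a free end to start from; none -> cycle -> drop
    start <- NULL
    for (b in sort(comp)) for (e in 1:2) {
      if (is.null(conn[[b]][[e]]) && is.null(start)) start <- c(b, e)
    }
    if (is.null(start)) next
    path <- NULL; labels <- integer(0)
    b <- start[1]; enter <- start[2]
    repeat {
      br <- branches[[b]]
      p <- br$path; l <- br$labels
      if (enter == 2) {
        p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        l <- rev(l)
      }
      path <- rbind(path, p)
      labels <- c(labels, l)
      exit <- if (enter == 1) 2 else 1
      link <- conn[[b]][[exit]]
      if (is.null(link)) break
      if (nrow(link$path) > 2) {
        mid <- link$path[-c(1, nrow(link$path)), , drop = FALSE]
        path <- rbind(path, mid)
        labels <- c(labels, rep(link$label, nrow(mid)))
      }
      b <- link$branch
      enter <- link$end
    }
    fib <- build_fiber(path, labels, min_segment_px)
    if (is.null(fib)) next
    if (length(unique(fib$segments$label)) < 2) next
    if (naive_path_length(fib$path) < min_total_px) next
    fibers[[length(fibers) + 1]] <- fib
  }
  fibers
}

# Segment runs (with short-run absorption) and the fiber object itself.
build_fiber <- function(path, labels, min_segment_px = 5) {
  keep <- labels > 0
  if (sum(keep) < 2) return(NULL)
  path <- path[keep, , drop = FALSE]
  labels <- labels[keep]
  r <- rle(labels)
  while (length(r$lengths) > 1 && any(r$lengths < min_segment_px)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_segment_px) break
    nb <- c(if (i > 1) i - 1, if (i < length(r$lengths)) i + 1)
    j <- nb[which.max(r$lengths[nb])]
    r$values[i] <- r$values[j]
    labels <- inverse.rle(r)
    r <- rle(labels)
  }
  labels <- inverse.rle(r)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  seg_len <- vapply(seq_along(starts), function(k) {
    naive_path_length(path[starts[k]:ends[k], , drop = FALSE])
  }, numeric(1))
  structure(list(path = path, labels = labels,
                 segments = data.frame(label = r$values, n_px = r$lengths,
                                       length_px = seg_len),
                 total_px = nrow(path)),
            class = "fiber")
}

#' Final fiber cleaning
#'
#' Keeps fibers that are bicolor (exactly two distinct analog labels), have
#' two or three segments, and stay clear of the image border (no skeleton
#' pixel within `border_margin` pixels of an edge); everything else --
#' single-label tracks, structures with more than three segments, and
#' border-cropped fibers -- is discarded.
#'
#' @param fibers fiber list from [reconnect_and_group()].
#' @param image_dim `c(rows, cols)`.
#' @param border_margin border exclusion margin in pixels (default 1).
#' @return filtered fiber list.
#' @export
clean_fibers <- function(fibers, image_dim, border_margin = 1) {
  Filter(function(f) {
    if (length(unique(f$segments$label)) != 2) return(FALSE)
    ns <- nrow(f$segments)
    if (ns < 2 || ns > 3) return(FALSE)
    if (any(f$path[, 1] <= border_margin) ||
        any(f$path[, 1] > image_dim[1] - border_margin) ||
        any(f$path[, 2] <= border_margin) ||
        any(f$path[, 2] > image_dim[2] - border_margin)) return(FALSE)
    TRUE
  }, fibers)
}

#' Reconstruct fibers from a class mask
#'
#' The full disentanglement chain: skeletonize, detect and cluster
#' junctions, erase junction regions and split into branches, estimate
#' endpoint directions, match endpoints across junctions, reconnect and
#' group into fibers, and apply final cleaning.
#'
#' @param mask integer class mask (`{0, 1, 2}`).
#' @param junction_cluster_px single-linkage threshold (default 10).
#' @param radius_factor junction erasure radius as a multiple of the fiber
#'   width (default 1.5).
#' @param min_branch_px minimum branch size (default 5).
#' @param trace_px endpoint direction trace length (default 15).
#' @param max_dist_factor matching radius as a multiple of the fiber width
#'   (default 3).
#' @param weights matching cost weights (distance, angle, color).
#' @param min_total_px minimum fiber length in pixels (default 15).
#' @param min_segment_px minimum reported segment run (default 5).
#' @param border_margin border exclusion margin (default 1).
#' @return list with `fibers` (cleaned), `all_fibers` (before cleaning),
#'   `branches`, `junctions`, `skeleton`.
#' @export
reconstruct_fibers <- function(mask, junction_cluster_px = 10,
                               radius_factor = 1.5, min_branch_px = 5,
                               trace_px = 15, max_dist_factor = 3,
                               weights = c(0.15, 0.65, 0.2),
                               min_total_px = 15, min_segment_px = 5,
                               border_margin = 1) {
  sk <- skeletonize(mask)
  jpx <- detect_junctions(sk)
  junctions <- cluster_junctions(jpx, junction_cluster_px)
  if (nrow(junctions) > 1)
    junctions <- merge_close_junctions(junctions,
                                       max(2, radius_factor * sk$width))
  branches <- erase_and_split(sk, junctions, radius_factor, min_branch_px,
                              trace_px)
  matches <- match_all_junctions(branches, junctions, sk$width,
                                 max_dist_factor, weights)
  fibers <- reconnect_and_group(branches, matches, min_total_px,
                                min_segment_px)
  cleaned <- clean_fibers(fibers, dim(mask), border_margin)
  cleaned <- lapply(cleaned, function(f) {
    f$end_ext <- c(tip_extension(f$path, 1, mask, sk$width),
                   tip_extension(f$path, 2, mask, sk$width))
    f
  })
  list(fibers = cleaned, all_fibers = fibers, branches = branches,
       junctions = junctions, skeleton = sk)
}

# Thinning retracts skeleton tips inside the rounded stroke cap. Walk from
# the terminal path pixel along the outward direction until the mask ends;
# the distance to the cap boundary minus the half-width estimates how far
# the true fiber end lies beyond the skeleton tip. Clamped to [0, w/2].
tip_extension <- function(path, end, mask, width) {
  n <- nrow(path)
  if (n < 3) return(0)
  a <- endpoint_direction(list(path = path), end, trace_px = 8)
  u <- c(-sin(a), cos(a))  # (row, col) step for angle convention
  t0 <- path[if (end == 1) 1 else n, ]
  d <- dim(mask)
  s <- seq(0.5, max(1, width), by = 0.5)
  e <- 0
  for (si in s) {
    p <- round(t0 + si * u)
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2]) break
    if (mask[p[1], p[2]] == 0) break
    e <- si
  }
  clamp(e - width / 2, 0, width / 2)
}
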