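# Detection evaluation: greedy IoU matching, precision/recall/F1,
# multiclass Dice, and skeleton-proximity agreement between graders.

#' Pixel set of a fiber for IoU computations
#'
#' Dilates the fiber's centerline by the annotation stroke radius so that
#' predictions are commensurate with ground-truth stroke masks.
#'
#' @param path n x 2 pixel path (or a fiber object).
#' @param image_dim `c(rows, cols)`.
#' @param radius dilation radius (default 3, the annotation pencil radius);
#'   `0` gives the raw centerline pixels.
#' @return sorted integer vector of linear pixel indices.
#' @export
fiber_pixel_set <- function(path, image_dim, radius = 3) {
  if (inherits(path, "fiber") || is.list(path)) path <- path$path
  pad <- ceiling(radius) + 1
  r0 <- max(1, min(path[, 1]) - pad)
  c0 <- max(1, min(path[, 2]) - pad)
  r1 <- min(image_dim[1], max(path[, 1]) + pad)
  c1 <- min(image_dim[2], max(path[, 2]) + pad)
  m <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
  lp <- cbind(path[, 1] - r0 + 1, path[, 2] - c0 + 1)
  if (radius > 0) m <- stamp_discs(m, lp, radius)
  else m[lp] <- TRUE
  idx <- which(m, arr.ind = TRUE)
  sort((idx[, 2] + c0 - 2) * image_dim[1] + idx[, 1] + r0 - 1)
}

iou <- function(a, b) {
  i <- length(intersect(a, b))
  u <- length(a) + length(b) - i
  if (u == 0) 0 else i / u
}

#' Greedy one-to-one detection matching by decreasing IoU
#'
#' All prediction/ground-truth pairs with IoU above the threshold are
#' sorted by decreasing IoU (ties broken by prediction id, then ground
#' truth id) and accepted greedily when both members are still unmatched,
#' enforcing a one-to-one correspondence.
#'
#' @param pred,gt lists of pixel-index sets (see [fiber_pixel_set()]).
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return list of class `match_result`: `matches` (data.frame `pred`,
#'   `gt`, `iou`), `unmatched_pred` (false positives), `unmatched_gt`
#'   (false negatives).
#' @export
match_detections <- function(pred, gt, iou_threshold = 0.5) {
  np <- length(pred); ng <- length(gt)
  # cheap index-range prefilter: disjoint ranges cannot overlap
  prng <- vapply(pred, function(s) if (length(s)) range(s) else c(1, 0),
                 numeric(2))
  grng <- vapply(gt, function(s) if (length(s)) range(s) else c(1, 0),
                 numeric(2))
  cand <- NULL
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    if (prng[2, i] < grng[1, j] || grng[2, j] < prng[1, i]) next
    v <- iou(pred[[i]], gt[[j]])
    if (v > iou_threshold) cand <- rbind(cand, c(i, j, v))
  }
  matches <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    used_p <- logical(np); used_g <- logical(ng)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_p[i] || used_g[j]) next
      used_p[i] <- TRUE; used_g[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(pred = i, gt = j, iou = cand[r, 3]))
    }
  }
  structure(list(matches = matches,
                 unmatched_pred = setdiff(seq_len(np), matches$pred),
                 unmatched_gt = setdiff(seq_len(ng), matches$gt)),
            class = "match_result")
}

#' Detection precision, recall and F1
#'
#' @param match a [match_detections()] result.
#' @return named numeric vector `precision`, `recall`, `f1`; empty
#'   denominators yield 0 with a warning.
#' @export
detection_prf <- function(match) {
  tp <- nrow(match$matches)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  if (tp + fp == 0 || tp + fn == 0 || tp == 0) {
    if (tp + fp == 0 || tp + fn == 0)
      warning("empty denominator in precision/recall; reporting 0")
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    return(c(precision = p, recall = r, f1 = 0))
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  c(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

#' Multiclass Dice score between two class masks
#'
#' Mean over foreground classes (analog 1, analog 2) of
#' `2|A n B| / (|A| + |B|)`; a class absent from both masks is skipped.
#'
#' @param pred,gt integer class masks of identical dimension.
#' @return Dice score in `[0, 1]` (`NaN` when no foreground class occurs).
#' @export
multiclass_dice <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("mask shapes differ")
  scores <- c()
  for (k in 1:2) {
    a <- pred == k; b <- gt == k
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0) next
    scores <- c(scores, 2 * sum(a & b) / (na + nb))
  }
  mean(scores)
}

#' Skeleton-proximity agreement between two fiber sets
#'
#' Two fibers are "common" to both graders when at least `min_fraction` of
#' each one's skeleton pixels lie within `dist` pixels of the other's
#' skeleton (mutual criterion; the comparison is symmetric and the
#' fraction test is inclusive).
#'
#' @param fibers_a,fibers_b lists of n x 2 skeleton pixel matrices (or
#'   fiber objects).
#' @param dist proximity distance in pixels (default 5).
#' @param min_fraction minimum covered fraction (default 0.5).
#' @return data.frame `a`, `b` of common-fiber index pairs.
#' @export
skeleton_agreement <- function(fibers_a, fibers_b, dist = 5,
                               min_fraction = 0.5) {
  as_px <- function(f) if (is.list(f) && !is.null(f$path)) f$path else f
  fibers_a <- lapply(fibers_a, as_px)
  fibers_b <- lapply(fibers_b, as_px)
  frac_near <- function(p, q, d) {
    # fraction of p's pixels within d of q
    mind2 <- vapply(seq_len(nrow(p)), function(i) {
      min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)
    }, numeric(1))
    mean(mind2 <= d^2)
  }
  out <- data.frame(a = integer(0), b = integer(0))
  for (i in seq_along(fibers_a)) for (j in seq_along(fibers_b)) {
    if (frac_near(fibers_a[[i]], fibers_b[[j]], dist) >= min_fraction &&
        frac_near(fibers_b[[j]], fibers_a[[i]], dist) >= min_fraction)
      out <- rbind(out, data.frame(a = i, b = j))
  }
  out
}

#' Count fibers found by k other graders
#'
#' For each grader, counts how many of their fibers are common (per
#' [skeleton_agreement()]) with exactly 0, 1, ..., n-1 of the other
#' graders' fiber sets.
#'
#' @param grader_fibers list (one element per grader) of fiber-path lists.
#' @param dist,min_fraction agreement parameters.
#' @return matrix: rows graders, columns `found_by_0` ... `found_by_k`.
#' @export
agreement_histogram <- function(grader_fibers, dist = 5,
                                min_fraction = 0.5) {
  n <- length(grader_fibers)
  out <- matrix(0L, n, n,
                dimnames = list(paste0("grader_", seq_len(n)),
                                paste0("found_by_", seq_len(n) - 1)))
  for (g in seq_len(n)) {
    counts <- integer(length(grader_fibers[[g]]))
    for (h in setdiff(seq_len(n), g)) {
      pairs <- skeleton_agreement(grader_fibers[[g]], grader_fibers[[h]],
                                  dist, min_fraction)
      counts[unique(pairs$a)] <- counts[unique(pairs$a)] + 1L
    }
    for (k in 0:(n - 1)) out[g, k + 1] <- sum(counts == k)
  }
  out
}
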