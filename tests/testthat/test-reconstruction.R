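# Skeletonization, junction detection/clustering, branch splitting,
# endpoint matching, reconnection and cleaning.

hline_mask <- function(size, row, cols, radius = 3, label = 1L) {
  m <- matrix(0L, size[1], size[2])
  pts <- rbind(c(row, cols[1]), c(row, cols[2]))
  m[fibertrace:::rasterize_stroke(pts, radius, size)] <- label
  m
}

test_that("skeleton of a straight stroke is a single path of correct length", {
  m <- hline_mask(c(60, 80), 30, c(15, 65))  # 50 px long stroke
  sk <- skeletonize(m)
  lab <- fibertrace:::label_components(sk$skeleton, 8L)
  expect_equal(max(lab), 1)
  px <- which(sk$skeleton, arr.ind = TRUE)
  path <- px[fibertrace:::order_component_path(px), ]
  expect_lte(abs(fibertrace:::naive_path_length(path) - 50), 2)
  # estimated width ~ stroke diameter
  expect_gt(sk$width, 4)
  expect_lt(sk$width, 9)
})

test_that("skeletonize handles the empty mask and a filled blob", {
  sk <- skeletonize(matrix(0L, 20, 20))
  expect_false(any(sk$skeleton))
  # filled disc of radius 5 collapses to (nearly) a point
  m <- matrix(0L, 30, 30)
  g <- as.matrix(expand.grid(r = 1:30, c = 1:30))
  m[g[(g[, 1] - 15)^2 + (g[, 2] - 15)^2 <= 25, ]] <- 1L
  sk <- skeletonize(m)
  expect_lte(sum(sk$skeleton), 3)
})

test_that("skeleton pixels inherit mask labels", {
  m <- hline_mask(c(40, 80), 20, c(10, 70), label = 2L)
  sk <- skeletonize(m)
  expect_true(all(sk$labels[sk$skeleton] == 2L))
})

test_that("junction templates: line, cross, and T", {
  m <- hline_mask(c(80, 80), 40, c(10, 70))
  expect_equal(nrow(detect_junctions(skeletonize(m))), 0)

  cross <- m
  pts <- rbind(c(10, 40), c(70, 40))
  cross[fibertrace:::rasterize_stroke(pts, 3, c(80, 80))] <- 1L
  jp <- detect_junctions(skeletonize(cross))
  expect_gt(nrow(jp), 0)
  expect_true(all(sqrt((jp[, 1] - 40)^2 + (jp[, 2] - 40)^2) <= 8))

  tee <- m
  pts <- rbind(c(40, 40), c(75, 40))
  tee[fibertrace:::rasterize_stroke(pts, 3, c(80, 80))] <- 1L
  jt <- detect_junctions(skeletonize(tee))
  expect_gt(nrow(jt), 0)
  expect_true(all(sqrt((jt[, 1] - 40)^2 + (jt[, 2] - 40)^2) <= 8))
})

test_that("oracle: crossing-number junctions equal brute neighbour analysis", {
  set.seed(21)
  for (rep in 1:5) {
    sk_m <- matrix(FALSE, 25, 25)
    sk_m[cbind(sample(5:20, 12, TRUE), sample(5:20, 12, TRUE))] <- TRUE
    sk <- list(skeleton = sk_m)
    jp <- detect_junctions(structure(sk, class = "skeleton_graph"))
    # brute force: count neighbour runs around the ring for every pixel
    ring <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                  c(0, -1), c(-1, -1))
    expected <- NULL
    for (r in 2:24) for (cc in 2:24) {
      if (!sk_m[r, cc]) next
      v <- vapply(seq_len(8), function(k)
        sk_m[r + ring[k, 1], cc + ring[k, 2]], logical(1))
      trans <- sum(!v & c(v[-1], v[1]))
      if (sum(v) >= 3 && trans >= 3) expected <- rbind(expected, c(r, cc))
    }
    if (is.null(expected)) expected <- matrix(integer(0), 0, 2)
    expect_equal(unname(jp), unname(expected))
  }
})

test_that("single-linkage clustering matches thresholds and chains", {
  expect_equal(nrow(cluster_junctions(rbind(c(10, 10), c(10, 15)), 10)), 1)
  expect_equal(nrow(cluster_junctions(rbind(c(10, 10), c(10, 30)), 10)), 2)
  # chain of 5 pixels at spacing 8 spans 32 px but chains into one cluster
  chain <- cbind(rep(10, 5), seq(10, 42, by = 8))
  expect_equal(nrow(cluster_junctions(chain, 10)), 1)
})

test_that("oracle: single-linkage clustering equals brute agglomeration", {
  set.seed(31)
  for (rep in 1:20) {
    pts <- cbind(runif(12, 0, 60), runif(12, 0, 60))
    got <- cluster_junctions(pts, 10)
    oracle <- brute_single_linkage(pts, 10)
    expect_equal(nrow(got), length(oracle))
  }
})

test_that("erase_and_split: line stays whole, X yields four branches", {
  m <- hline_mask(c(80, 80), 40, c(10, 70))
  sk <- skeletonize(m)
  br <- erase_and_split(sk, matrix(integer(0), 0, 2))
  expect_length(br, 1)
  expect_lte(abs(br[[1]]$length_px - 60), 3)

  cross <- m
  cross[fibertrace:::rasterize_stroke(rbind(c(10, 40), c(70, 40)), 3,
                                      c(80, 80))] <- 1L
  sk <- skeletonize(cross)
  j <- cluster_junctions(detect_junctions(sk), 10)
  br <- erase_and_split(sk, j)
  expect_length(br, 4)
})

test_that("short branches are discarded", {
  m <- hline_mask(c(30, 30), 15, c(12, 13), radius = 1)  # tiny stub
  sk <- skeletonize(m)
  expect_length(erase_and_split(sk, matrix(integer(0), 0, 2),
                                min_branch_px = 5), 0)
})

test_that("endpoint directions follow the row/col angle convention", {
  # horizontal branch: right endpoint points right (angle 0)
  path <- cbind(rep(10, 30), 1:30)
  br <- list(path = path)
  expect_equal(endpoint_direction(br, 2), 0, tolerance = 1e-6)
  expect_equal(abs(endpoint_direction(br, 1)), pi, tolerance = 1e-6)
  # vertical branch walked downward: the top endpoint (start) points up
  vpath <- cbind(5:40, rep(7, 36))
  expect_equal(endpoint_direction(list(path = vpath), 1), pi / 2,
               tolerance = 1e-6)
  expect_equal(endpoint_direction(list(path = vpath), 2), -pi / 2,
               tolerance = 1e-6)
})

test_that("endpoint direction equals the trailing chord of an arc", {
  # quarter circle of radius 40: angle at the end equals the 15-px chord
  th <- seq(0, pi / 2, length.out = 200)
  arc <- cbind(50 - 40 * sin(th), 50 + 40 * cos(th) - 40)
  ipath <- unique(round(arc))
  a <- endpoint_direction(list(path = ipath), 2, trace_px = 15)
  n <- nrow(ipath)
  chord <- fibertrace:::point_angle(ipath[n - 15, ], ipath[n, ])
  expect_equal(a, chord, tolerance = 1e-9)
})

test_that("matching joins collinear continuations across a crossing", {
  # red fiber crosses a green fiber at 90 degrees: within each fiber the
  # endpoint labels agree, so collinear same-color pairing must win
  eps <- data.frame(branch = 1:4, end = 1L,
                    row = c(40, 40, 30, 50),
                    col = c(30, 50, 40, 40),
                    angle = c(0, pi, -pi / 2, pi / 2),
                    label = c(1L, 1L, 2L, 2L))
  m <- match_endpoints(c(40, 40), eps, max_dist = 20)
  pairs <- m$pairs[order(m$pairs[, 1]), , drop = FALSE]
  expect_equal(pairs, rbind(c(1L, 2L), c(3L, 4L)), ignore_attr = TRUE)
})

test_that("two endpoints always pair; three leave a tip", {
  eps2 <- data.frame(branch = 1:2, end = 1L, row = c(10, 12),
                     col = c(10, 14), angle = c(0, pi), label = c(1L, 1L))
  m2 <- match_endpoints(c(11, 12), eps2, max_dist = 20)
  expect_equal(nrow(m2$pairs), 1)
  expect_length(m2$tips, 0)

  eps3 <- rbind(eps2, data.frame(branch = 3L, end = 1L, row = 6, col = 12,
                                 angle = -pi / 2, label = 2L))
  m3 <- match_endpoints(c(11, 12), eps3, max_dist = 20)
  expect_equal(nrow(m3$pairs), 1)
  expect_length(m3$tips, 1)
  expect_equal(m3$tips, 3L)
})

test_that("four-endpoint matching equals exhaustive enumeration", {
  set.seed(41)
  w <- c(0.15, 0.65, 0.2)
  for (rep in 1:25) {
    eps <- data.frame(branch = 1:4, end = 1L,
                      row = runif(4, 0, 30), col = runif(4, 0, 30),
                      angle = runif(4, -pi, pi),
                      label = sample(1:2, 4, TRUE))
    md <- 25
    cost <- function(i, j) {
      d <- sqrt((eps$row[i] - eps$row[j])^2 + (eps$col[i] - eps$col[j])^2)
      ang <- abs(pi - abs(fibertrace:::wrap_angle(eps$angle[i] -
                                                    eps$angle[j]))) / pi
      w[1] * d / md + w[2] * ang + w[3] * (eps$label[i] != eps$label[j])
    }
    totals <- c(cost(1, 2) + cost(3, 4), cost(1, 3) + cost(2, 4),
                cost(1, 4) + cost(2, 3))
    m <- match_endpoints(c(15, 15), eps, max_dist = md, weights = w)
    got <- sum(apply(m$pairs, 1, function(p) cost(p[1], p[2])))
    expect_equal(got, min(totals), tolerance = 1e-12)
  }
})

test_that("matching cost arithmetic verified by hand on one instance", {
  eps <- data.frame(branch = 1:2, end = 1L, row = c(0, 0), col = c(0, 10),
                    angle = c(0, pi), label = c(1L, 2L))
  w <- c(0.4, 0.4, 0.2)
  # cost(1,2) = 0.4 * 10/20 + 0.4 * |pi - pi|/pi + 0.2 * 1 = 0.4
  m <- match_endpoints(c(0, 5), eps, max_dist = 20, weights = w)
  expect_equal(nrow(m$pairs), 1)
  # add a collinear same-label endpoint at distance 19:
  #   cost(1,3) = 0.4 * 19/20 + 0 + 0          = 0.38  <- minimum
  #   cost(2,3) = 0.4 *  9/20 + 0.4 * 1 + 0.2  = 0.78
  # the 3-endpoint rule must pick (1,3) and leave 2 as the tip
  eps3 <- rbind(eps, data.frame(branch = 3L, end = 1L, row = 0, col = 19,
                                angle = pi, label = 1L))
  m3 <- match_endpoints(c(0, 5), eps3, max_dist = 20, weights = w)
  expect_equal(sort(m3$pairs[1, ]), c(1, 3))
  expect_equal(m3$tips, 2L)
})

test_that("reconnection colors and grouping rules", {
  # two collinear branches with different labels across one junction
  size <- c(40, 120)
  m <- matrix(0L, size[1], size[2])
  m[fibertrace:::rasterize_stroke(rbind(c(20, 10), c(20, 50)), 3, size)] <- 1L
  m[fibertrace:::rasterize_stroke(rbind(c(20, 70), c(20, 110)), 3, size)] <- 2L
  sk <- skeletonize(m)
  branches <- erase_and_split(sk, matrix(integer(0), 0, 2))
  expect_length(branches, 2)
  # fabricate a junction midway and match
  matches <- fibertrace:::match_all_junctions(branches,
                                              matrix(c(20L, 60L), 1),
                                              width = sk$width,
                                              max_dist_factor = 3)
  fibers <- reconnect_and_group(branches, matches)
  expect_length(fibers, 1)
  # reconnection pixels between cols 50 and 70 carry the second analog
  mid <- fibers[[1]]$labels[fibers[[1]]$path[, 2] > 52 &
                              fibers[[1]]$path[, 2] < 68]
  expect_true(all(mid == 2L))
})

test_that("single-label and short components are discarded in grouping", {
  size <- c(40, 120)
  m <- matrix(0L, size[1], size[2])
  m[fibertrace:::rasterize_stroke(rbind(c(20, 10), c(20, 110)), 3, size)] <- 1L
  rec <- reconstruct_fibers(m, border_margin = 0)
  expect_length(rec$all_fibers, 0)  # 100-px single-label: dropped

  # a 13-px bicolor branch is below the 15-px minimum at grouping
  path13 <- cbind(rep(20, 13), 5:17)
  raster <- matrix(0L, 40, 40)
  raster[path13] <- c(rep(1L, 6), rep(2L, 7))
  br <- fibertrace:::make_branch(1L, path13, raster)
  expect_length(reconnect_and_group(list(br), list()), 0)
})

test_that("final cleaning enforces bicolor, 2-3 segments, and borders", {
  mkfiber <- function(labels_runs, row = 20) {
    labels <- unlist(mapply(rep, labels_runs, 10))
    path <- cbind(rep(row, length(labels)), seq_along(labels) + 4)
    fibertrace:::build_fiber(path, labels, min_segment_px = 5)
  }
  dim40 <- c(40, 80)
  f4 <- mkfiber(c(1, 2, 1, 2))
  expect_length(clean_fibers(list(f4), dim40), 0)
  f2 <- mkfiber(c(1, 2))
  expect_length(clean_fibers(list(f2), dim40), 1)
  f_border <- mkfiber(c(1, 2), row = 1)
  expect_length(clean_fibers(list(f_border), dim40), 0)
  f3 <- mkfiber(c(2, 1, 2))
  expect_length(clean_fibers(list(f3), dim40), 1)
})

test_that("planted crossings are disentangled into two accurate fibers", {
  # spot-check three seeds here; the acceptance suite covers 50
  for (s in c(101, 202, 303)) {
    cp <- crossing_pair(s)
    r <- clean_render(cp$gt, c(300, 300))
    res <- suppressWarnings(analyze_fluor_image(r$image, pipeline_config()))
    se <- segment_errors(cp$gt, res$fibers, c(300, 300))
    expect_equal(nrow(se$match$matches), 2)
  }
})
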