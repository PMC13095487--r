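# Fiber measurement, classification, features and the error filter.

# Build a fiber object from explicit horizontal runs (no tip corrections).
runs_fiber <- function(runs, row = 10) {
  labels <- unlist(mapply(function(l, n) rep(l, n), runs$label, runs$n))
  path <- cbind(rep(row, length(labels)), seq_along(labels))
  fibertrace:::build_fiber(path, labels, min_segment_px = 2)
}

test_that("equal 50/50 horizontal fiber measures 12.74 um per segment", {
  f <- runs_fiber(data.frame(label = c(1, 2), n = c(50, 50)))
  m <- measure_fiber(f, pixel_size = 0.26)
  expect_equal(m$segments$length_um[1], 12.74, tolerance = 0.26 / 12.74)
  expect_equal(m$segments$length_um[2], 12.74, tolerance = 0.26 / 12.74)
  expect_equal(m$ratio, 1, tolerance = 0.05)
  expect_equal(m$type, "ongoing_fork")
})

test_that("naive estimator gives n*sqrt(2) on a pure diagonal run", {
  n <- 40
  path <- cbind(1:(n + 1), 1:(n + 1))
  labels <- c(rep(1L, 20), rep(2L, n + 1 - 20))
  f <- fibertrace:::build_fiber(path, labels, min_segment_px = 2)
  m <- measure_fiber(f, pixel_size = 0.26, estimator = "naive")
  expect_equal(m$total_um, n * sqrt(2) * 0.26, tolerance = 1e-9)
})

test_that("measured total length tracks planted arc length within 3%", {
  sl <- clean_slide(10, c(500, 500), seed = 17)
  res <- analyze_fluor_image(sl$rendered$image, pipeline_config())
  se <- segment_errors(sl$gt, res$fibers, c(500, 500))
  for (k in seq_len(nrow(se$match$matches))) {
    g <- sl$gt[[se$match$matches$gt[k]]]
    mm <- measure_fiber(res$fibers[[se$match$matches$pred[k]]], 1)
    expect_lt(abs(mm$total_um - g$arc_length_px) / g$arc_length_px, 0.03)
  }
})

test_that("structure classification covers the full catalogue", {
  expect_equal(classify_structure(c(1L, 2L)), "ongoing_fork")
  expect_equal(classify_structure(c(2L, 1L)), "ongoing_fork")
  expect_equal(classify_structure(c(2L, 1L, 2L)), "divergent_origin")
  expect_equal(classify_structure(c(1L, 2L, 1L)), "convergent_fork")
  expect_equal(classify_structure(c(1L, 1L)), "invalid")
  expect_equal(classify_structure(c(2L, 2L, 2L)), "invalid")
  expect_equal(classify_structure(c(1L, 2L, 1L, 2L)), "invalid")
})

test_that("zero-length segments mark the record invalid, not an error", {
  f <- runs_fiber(data.frame(label = c(1, 2), n = c(50, 50)))
  f$segments$n_px[2] <- 0L
  m <- measure_fiber(f, 0.26)
  expect_false(m$valid)
})

test_that("features: straight fiber, uniform intensity, closed loop", {
  f <- runs_fiber(data.frame(label = c(1, 2), n = c(30, 30)), row = 20)
  img <- fluor_image(matrix(70, 40, 70), matrix(70, 40, 70))
  ft <- fiber_features(f, img)
  expect_equal(ft$tortuosity, 1, tolerance = 1e-9)
  expect_equal(ft$mean_curvature, 0, tolerance = 1e-9)
  expect_equal(ft$mean_intensity1, 70)
  expect_equal(ft$mean_intensity2, 70)
  # closed loop: infinite tortuosity sentinel
  th <- seq(0, 2 * pi, length.out = 100)
  loop <- unique(round(cbind(20 + 10 * sin(th), 35 + 10 * cos(th))))
  loop <- rbind(loop, loop[1, ])  # closed: identical endpoints
  ft2 <- fiber_features(list(path = loop), img)
  expect_true(is.infinite(ft2$tortuosity))
  expect_equal(default_error_scorer()(ft2), 1)
})

test_that("semicircle tortuosity approaches pi/2", {
  th <- seq(0, pi, length.out = 300)
  poly <- cbind(60 - 40 * sin(th), 60 + 40 * cos(th))
  m <- matrix(0L, 120, 120)
  m[fibertrace:::rasterize_stroke(poly, 3, c(120, 120))] <- 1L
  sk <- skeletonize(m)
  px <- which(sk$skeleton, arr.ind = TRUE)
  path <- px[fibertrace:::order_component_path(px), ]
  ft <- fiber_features(list(path = path),
                       fluor_image(m * 100, m * 0))
  expect_equal(ft$tortuosity, pi / 2, tolerance = 0.1)
  # chord curvature approaches 1/r
  expect_lt(abs(ft$mean_curvature - 1 / 40), 0.012)
})

test_that("the default scorer separates straight fibers from zigzags", {
  scorer <- default_error_scorer()
  straight <- list(tortuosity = 1.02, mean_curvature = 0.01,
                   mean_intensity1 = 150, mean_intensity2 = 140)
  zigzag <- list(tortuosity = 2.4, mean_curvature = 0.5,
                 mean_intensity1 = 150, mean_intensity2 = 140)
  expect_lt(scorer(straight), 0.5)
  expect_gt(scorer(zigzag), scorer(straight))
  expect_gt(scorer(zigzag), 0.5)
  faint <- list(tortuosity = 1.0, mean_curvature = 0,
                mean_intensity1 = 5, mean_intensity2 = 4)
  expect_gt(scorer(faint), 0.5)
})

test_that("error filtering is monotone in the threshold", {
  set.seed(51)
  records <- data.frame(error_prob = runif(50), valid = TRUE)
  r03 <- apply_error_filter(records, 0.3)
  r05 <- apply_error_filter(records, 0.5)
  r10 <- apply_error_filter(records, 1.0)
  expect_true(all(which(!r05$valid) %in% which(!r03$valid)))
  expect_true(all(r10$valid))
})
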