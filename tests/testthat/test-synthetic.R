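# Synthetic fiber generator: geometry sampling, rendering, ground truth.

test_that("generate_fiber_set honours counts, determinism and ratios", {
  expect_length(generate_fiber_set(0, c(100, 100), seed = 1), 0)

  g1 <- generate_fiber_set(15, c(400, 400), seed = 7)
  g2 <- generate_fiber_set(15, c(400, 400), seed = 7)
  expect_identical(g1, g2)
  expect_length(g1, 15)

  # fixed ratio 1, two segments only: every fiber splits 50/50
  geom <- fiber_geometry(segment_count_probs = c(0, 1, 0),
                         ratio_dist = list(type = "fixed", value = 1.0))
  gt <- generate_fiber_set(100, c(900, 900), geom, seed = 3)
  fr <- t(vapply(gt, function(f) f$segments$fraction, numeric(2)))
  expect_equal(fr[, 1], rep(0.5, 100), tolerance = 1e-12)
  expect_equal(fr[, 2], rep(0.5, 100), tolerance = 1e-12)
})

test_that("invalid generator parameters are rejected", {
  expect_error(fiber_geometry(length_range = c(100, 50)), "min > max")
  expect_error(fiber_geometry(max_turn_deg = -1), "non-negative")
  expect_error(render_params(image_size = c(0, 10)), "zero-size")
})

test_that("fiber invariants hold: fractions sum to 1, lengths consistent", {
  gt <- generate_fiber_set(50, c(600, 600), fiber_geometry(), seed = 11)
  for (f in gt) {
    expect_equal(sum(f$segments$fraction), 1, tolerance = 1e-9)
    expect_gte(nrow(f$polyline), 2)
    expect_true(nrow(f$segments) %in% 1:3)
    # polyline arc length equals the sum of segment lengths
    expect_equal(sum(f$segments$fraction * f$arc_length_px),
                 fibertrace:::polyline_length(f$polyline),
                 tolerance = 1e-6)
  }
})

test_that("rendered stroke matches a brute-force rasterization oracle", {
  f <- straight_gt_fiber(c(20, 8), c(20, 52), fractions = 1, labels = 1L)
  r <- clean_render(list(f), c(40, 60))
  oracle <- brute_rasterize(f$polyline, 3, c(40, 60))
  expect_identical(unname(r$mask > 0), unname(oracle))
})

test_that("empty ground truth renders background only", {
  r <- clean_render(list(), c(50, 50))
  expect_true(all(r$mask == 0))
  expect_true(all(r$instance == 0))
  expect_equal(max(abs(r$image$data - 8)), 0)
})

test_that("two crossing fibers produce two instance ids", {
  a <- straight_gt_fiber(c(30, 10), c(30, 90))
  b <- straight_gt_fiber(c(10, 50), c(50, 50))
  r <- clean_render(list(a, b), c(60, 100))
  expect_setequal(setdiff(unique(as.vector(r$instance)), 0L), c(1L, 2L))
})

test_that("render is deterministic and masks are unaffected by degradation", {
  gt <- generate_fiber_set(6, c(200, 200), fiber_geometry(), seed = 2)
  p <- render_params(c(200, 200), psf_sigma = 1.2, noise_sigma = 6,
                     illumination_gradient = 0.25, seed = 9)
  r1 <- render_fibers(gt, p)
  r2 <- render_fibers(gt, p)
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(r1$mask, r2$mask)
  # same scene rendered clean: identical masks, different intensities
  r0 <- clean_render(gt, c(200, 200))
  expect_identical(r0$mask, r1$mask)
  expect_identical(r0$instance, r1$instance)
})

test_that("noise-free stroke pixels carry full fiber intensity", {
  gt <- generate_fiber_set(5, c(250, 250), fiber_geometry(), seed = 5)
  r <- clean_render(gt, c(250, 250))
  for (k in 1:2) {
    px <- r$mask == k
    if (!any(px)) next
    expect_true(all(r$image$data[, , k][px] >= 180 - 1e-9))
  }
})

test_that("transition pixels are assigned to the second analog", {
  # horizontal fiber, transition at column 30: the boundary band is green
  f <- straight_gt_fiber(c(20, 10), c(20, 50))
  r <- clean_render(list(f), c(40, 60))
  on_axis <- r$mask[20, 10:50]
  runs <- rle(on_axis[on_axis > 0])
  expect_identical(as.integer(runs$values), c(1L, 2L))
  # the exact midpoint pixel (ambiguous) is green
  expect_identical(r$mask[20, 30], 2L)
})

test_that("ground-truth table and synthetic slide files round-trip", {
  gt <- generate_fiber_set(4, c(200, 200), fiber_geometry(), seed = 13)
  tab <- ground_truth_table(gt, pixel_size = 0.26)
  expect_equal(nrow(tab), sum(vapply(gt, function(f) nrow(f$segments), 1L)))
  expect_equal(tab$length_um, tab$length_px * 0.26)

  out <- file.path(tempdir(), "slide-test")
  r <- clean_render(gt, c(200, 200))
  paths <- write_synthetic_slide(r, gt, out, prefix = "s1")
  expect_true(all(file.exists(paths)))
  img2 <- read_fluor_image(paths[1], pixel_size = 0.26)
  expect_equal(dim(img2), c(200, 200))
  m2 <- read_seg_mask(paths[2])
  expect_identical(m2, r$mask)
  unlink(out, recursive = TRUE)
})
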