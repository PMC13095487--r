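# Segmentation backends, tiled inference, TTA, ensembling.

# pixelwise (shift-invariant) backend used by several invariance tests
pixelwise_backend <- function(patch) {
  s1 <- patch[, , 1]; s2 <- patch[, , 2]
  tot <- s1 + s2 + 30
  out <- array(0, c(dim(patch)[1:2], 3))
  out[, , 1] <- 30 / tot
  out[, , 2] <- s1 / tot
  out[, , 3] <- s2 / tot
  out
}

test_that("threshold backend: all-zero patch is pure background", {
  b <- threshold_backend()
  p <- b(array(0, c(32, 32, 2)))
  expect_equal(p[, , 1], matrix(1, 32, 32), tolerance = 1e-9)
})

test_that("threshold backend classifies a clean channel-2 stroke", {
  f <- straight_gt_fiber(c(30, 10), c(30, 70), fractions = 1, labels = 2L)
  r <- clean_render(list(f), c(60, 80))
  b <- threshold_backend()
  p <- b(r$image$data)
  mask <- prob_to_mask(p)
  stroke <- r$mask == 2
  expect_gte(mean(mask[stroke] == 2), 0.99)
})

test_that("backend probabilities lie on the simplex", {
  set.seed(4)
  arr <- array(runif(48 * 48 * 2, 0, 200), c(48, 48, 2))
  for (b in list(threshold_backend(), threshold_backend(c(60, 60), 0))) {
    p <- b(arr)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(p[, , 1] + p[, , 2] + p[, , 3],
                 matrix(1, 48, 48), tolerance = 1e-6)
  }
})

test_that("tiled inference equals direct application for pixelwise backends", {
  set.seed(5)
  arr <- array(runif(300 * 260 * 2, 0, 120), c(300, 260, 2))
  spec <- tile_spec(tile = 128, overlap_fraction = 0.1)
  direct <- pixelwise_backend(arr)
  tiled <- tiled_inference(pixelwise_backend, arr, spec)
  expect_lt(max(abs(tiled - direct)), 1e-6)
})

test_that("tiled inference: single-tile image and constant image", {
  arr <- array(runif(64 * 64 * 2), c(64, 64, 2))
  spec <- tile_spec(tile = 64)
  expect_equal(tiled_inference(pixelwise_backend, arr, spec),
               pixelwise_backend(arr), tolerance = 1e-9)
  const <- array(50, c(200, 150, 2))
  out <- tiled_inference(pixelwise_backend, const, tile_spec(128))
  expect_lt(max(abs(sweep(out, 3, out[1, 1, ]))), 1e-9)
})

test_that("tiled inference preserves the probability simplex", {
  set.seed(6)
  arr <- array(runif(200 * 170 * 2, 0, 255), c(200, 170, 2))
  out <- tiled_inference(threshold_backend(), arr, tile_spec(96, 0.1))
  expect_equal(out[, , 1] + out[, , 2] + out[, , 3],
               matrix(1, 200, 170), tolerance = 1e-6)
})

test_that("TTA is exact for equivariant backends and constants", {
  set.seed(7)
  arr <- array(runif(60 * 60 * 2), c(60, 60, 2))
  expect_equal(tta_inference(pixelwise_backend, arr),
               pixelwise_backend(arr), tolerance = 1e-9)
  const_backend <- function(patch) {
    out <- array(0, c(dim(patch)[1:2], 3))
    out[, , 1] <- 0.2; out[, , 2] <- 0.3; out[, , 3] <- 0.5
    out
  }
  expect_equal(tta_inference(const_backend, arr), const_backend(arr))
  # non-square images use the flip subgroup only; still exact here
  arr2 <- array(runif(40 * 60 * 2), c(40, 60, 2))
  expect_equal(tta_inference(pixelwise_backend, arr2),
               pixelwise_backend(arr2), tolerance = 1e-9)
})

test_that("TTA output inherits the symmetry of a D4-symmetric input", {
  v <- matrix(0, 61, 61)
  v[31, ] <- 100; v[, 31] <- 100  # symmetric cross
  arr <- array(0, c(61, 61, 2)); arr[, , 1] <- v; arr[, , 2] <- v
  # an asymmetric backend: shifts mass by row index
  asym <- function(patch) {
    w <- row(patch[, , 1]) / nrow(patch[, , 1])
    out <- array(0, c(dim(patch)[1:2], 3))
    out[, , 1] <- 1 - w * 0.5
    out[, , 2] <- w * 0.25
    out[, , 3] <- w * 0.25
    out
  }
  out <- tta_inference(asym, arr)
  for (k in 1:3) {
    expect_lt(max(abs(out[, , k] - t(out[, , k]))), 1e-6)
    expect_lt(max(abs(out[, , k] - out[61:1, , k])), 1e-6)
  }
})

test_that("ensembling averages member maps", {
  set.seed(8)
  arr <- array(runif(40 * 40 * 2), c(40, 40, 2))
  b1 <- pixelwise_backend
  b2 <- function(patch) {
    p <- pixelwise_backend(patch)
    p[, , c(1, 3, 2)]
  }
  expect_equal(ensemble_inference(list(b1), arr), b1(arr))
  expect_equal(ensemble_inference(list(b1, b1), arr), b1(arr))
  expect_equal(ensemble_inference(list(b1, b2), arr),
               (b1(arr) + b2(arr)) / 2, tolerance = 1e-12)
  expect_error(ensemble_inference(list(), arr), "at least one")
})

test_that("argmax masks contain only classes 0..2", {
  set.seed(9)
  p <- array(runif(30 * 30 * 3), c(30, 30, 3))
  p <- p / array(rep(p[, , 1] + p[, , 2] + p[, , 3], 3), dim(p))
  m <- prob_to_mask(p)
  expect_true(all(m %in% 0:2))
})
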