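# Otsu binarization, GMR thresholding, polygon clipping, and foreground
# statistics.

test_that("otsuThreshold matches the exhaustive oracle and tie rule", {
  # two-spike histogram: variance is flat on [50, 199]; smallest t wins
  h <- numeric(256); h[51] <- 100; h[201] <- 100
  expect_identical(otsuThreshold(h), 50L)
  # bimodal mixtures against the brute-force argmax
  set.seed(101)
  for (rep in 1:25) {
    lo <- round(rnorm(400, mean = runif(1, 40, 90), sd = runif(1, 3, 15)))
    hi <- round(rnorm(300, mean = runif(1, 150, 220), sd = runif(1, 3, 15)))
    h <- tabulate(pmin(pmax(c(lo, hi), 0), 255) + 1L, nbins = 256L)
    expect_identical(otsuThreshold(h), oracleOtsu(h))
  }
  # arbitrary (not necessarily bimodal) histograms
  set.seed(202)
  for (rep in 1:25) {
    h <- rpois(256, lambda = runif(1, 0.5, 4))
    if (sum(h > 0) < 2) next
    expect_identical(otsuThreshold(h), oracleOtsu(h))
  }
  h1 <- numeric(256); h1[10] <- 500
  expect_error(otsuThreshold(h1), "degenerate")
  expect_error(otsuThreshold(numeric(10)), "256")
})

test_that("segmentLeaf recovers the leaf and picks the darker class", {
  sc <- generateLeafScan(2.3, sceneConfig("leaf", 96, 96, noiseSd = 8,
                                          seed = 21))
  m <- segmentLeaf(sc$image)
  expect_identical(maskMethod(m), "otsu")
  expect_gte(iou(m, sc$truth), 0.99)
  # constant white image has no bimodal structure
  white <- rgbImage(array(250L, dim = c(16, 16, 3)), "leaf")
  expect_error(segmentLeaf(white), "degenerate")
  # inverting the image swaps foreground and background
  inv <- rgbImage(255L - sc$image@data, "leaf")
  expect_identical(maskMatrix(segmentLeaf(inv)), !maskMatrix(m))
})

test_that("gmrMap is the signed unclipped difference G - R", {
  d <- array(0L, dim = c(2, 2, 3))
  d[1, 1, ] <- c(10L, 250L, 0L); d[1, 2, ] <- c(250L, 10L, 0L)
  d[2, 1, ] <- c(100L, 100L, 50L); d[2, 2, ] <- c(0L, 0L, 0L)
  img <- rgbImage(d, "canopy")
  gm <- gmrMap(img)
  expect_identical(gm[1, 1], 240L)
  expect_identical(gm[1, 2], -240L)
  expect_identical(gm[2, 1], 0L)
  # algebraic identity: map + R equals G elementwise
  expect_identical(gm + channel(img, "R"), channel(img, "G"))
})

test_that("segmentByGMR uses a strict threshold and is monotone", {
  d <- array(0L, dim = c(1, 2, 3))
  d[1, 1, ] <- c(100L, 100L, 0L)   # G - R = 0: background at threshold 0
  d[1, 2, ] <- c(100L, 101L, 0L)   # G - R = 1: foreground at threshold 0
  img <- rgbImage(d, "canopy")
  m0 <- segmentByGMR(img, 0)
  expect_identical(as.vector(maskMatrix(m0)), c(FALSE, TRUE))
  expect_identical(maskThreshold(m0), 0)
  # foreground count non-increasing as the threshold rises, on noisy scenes
  scn <- generateCanopyScene(2.4, sceneConfig("canopy", 64, 64,
                                              noiseSd = 20, seed = 31))
  counts <- vapply(c(0, 5, 10, 15, 20),
                   function(t) foregroundCount(segmentByGMR(scn$image, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation recovers generator truth at both noise levels", {
  for (noise in c(0, 8)) {
    tol <- if (noise == 0) 0.99 else 0.95
    leaf <- generateLeafScan(2.0, sceneConfig("leaf", 96, 96,
                                              noiseSd = noise, seed = 41))
    expect_gte(iou(segmentLeaf(leaf$image), leaf$truth), tol)
    can <- generateCanopyScene(2.0, sceneConfig("canopy", 96, 96,
                                                noiseSd = noise,
                                                seed = 42))
    expect_gte(iou(segmentByGMR(can$image, 5), can$truth), tol)
  }
})

test_that("foregroundChannelMeans matches a per-pixel loop oracle", {
  # constant image, any non-empty mask
  uni <- rgbImage(array(rep(c(10L, 20L, 30L), each = 12),
                        dim = c(3, 4, 3)), "canopy")
  m <- segmentationMask(matrix(c(TRUE, FALSE), 3, 4), "truth")
  got <- foregroundChannelMeans(uni, m)
  expect_equal(got[c("R", "G", "B")], c(R = 10, G = 20, B = 30))
  # half black, half (200, 100, 50), full mask
  d <- array(0L, dim = c(2, 2, 3))
  d[1, , ] <- matrix(rep(c(200L, 100L, 50L), each = 2), 2)
  img <- rgbImage(d, "canopy")
  got <- foregroundChannelMeans(img, fullMask(img))
  expect_equal(got[c("R", "G", "B")], c(R = 100, G = 50, B = 25))
  expect_equal(unname(got["n_foreground"]), 4)
  # random image and mask against naive accumulation
  set.seed(77)
  d <- array(sample(0:255, 10 * 8 * 3, TRUE), dim = c(10, 8, 3))
  img <- rgbImage(d, "canopy")
  mm <- matrix(runif(80) < 0.4, 10, 8)
  m <- segmentationMask(mm, "gmr", 5)
  acc <- c(0, 0, 0); n <- 0
  for (i in 1:10) for (j in 1:8) if (mm[i, j]) {
    acc <- acc + d[i, j, ]; n <- n + 1
  }
  expect_equal(unname(foregroundChannelMeans(img, m)),
               c(acc / n, n))
  # empty mask raises an error naming the method and threshold
  empty <- segmentationMask(matrix(FALSE, 10, 8), "gmr", 20)
  expect_error(foregroundChannelMeans(img, empty), "gmr.*20")
})

test_that("clipToPolygon follows the pixel-center even-odd rule", {
  img <- rgbImage(array(0L, dim = c(32, 32, 3)), "plot")
  # rectangle over pixel rows 10..19, cols 10..19: exactly 100 pixels
  rect <- matrix(c(10, 10, 10, 20, 20, 20, 20, 10), ncol = 2, byrow = TRUE)
  expect_equal(foregroundCount(clipToPolygon(img, rect)), 100)
  # whole-image polygon: all pixels inside
  whole <- matrix(c(0, 0, 0, 32, 32, 32, 32, 0), ncol = 2, byrow = TRUE)
  expect_true(all(maskMatrix(clipToPolygon(img, whole))))
  # random simple polygons against the scalar ray-cast oracle
  set.seed(55)
  for (rep in 1:5) {
    k <- sample(3:7, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 4, 14)
    poly <- cbind(16 + rad * sin(ang), 16 + rad * cos(ang))
    got <- maskMatrix(clipToPolygon(img, poly))
    for (i in seq(1, 32, by = 3)) for (j in seq(1, 32, by = 3)) {
      expect_identical(got[i, j],
                       oraclePointInPolygon(i - 0.5, j - 0.5, poly))
    }
  }
  expect_error(clipToPolygon(img, rect[1:2, ]), "3 vertices")
  degenerate <- matrix(c(5, 5, 5, 5, 5, 5), ncol = 2, byrow = TRUE)
  expect_error(clipToPolygon(img, degenerate), "zero area")
  outside <- matrix(c(-1, 0, 0, 40, 10, 10), ncol = 2, byrow = TRUE)
  expect_error(clipToPolygon(img, outside), "bounds")
})

test_that("clip-then-gmr equals gmr-then-clip on plot statistics", {
  mos <- generatePlotMosaic(c(2.2, 2.9),
                            sceneConfig("plot", 64, 64, seed = 8))
  poly <- mos$polygons[[1]]$vertices
  clip <- clipToPolygon(mos$image, poly)
  gmr <- segmentByGMR(mos$image, 5)
  a <- foregroundChannelMeans(mos$image, intersectMasks(clip, gmr))
  b <- foregroundChannelMeans(mos$image, intersectMasks(gmr, clip))
  expect_identical(a, b)
})
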