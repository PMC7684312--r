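# Decile piecewise-linear intensity normalization.

denseUniformImage <- function() {
  # 101-point uniform grid 0..100, replicated to fill a volume
  vals <- rep(0:100, length.out = 8 * 8 * 8)
  VolumeImage(array(as.numeric(vals), c(8, 8, 8)))
}

test_that("landmarks follow the linear-interpolation quantile convention", {
  img <- VolumeImage(array(as.numeric(0:100), c(101, 1, 1)))
  mask <- VoxelMask(array(TRUE, c(101, 1, 1)))
  lm <- computeLandmarks(img, mask)
  expect_equal(landmarkIntensities(lm)[landmarkPercentiles(lm) == 50], 50)
  expect_equal(landmarkIntensities(lm),
               unname(quantile(0:100, defaultLandmarkPercentiles() / 100)))
})

test_that("landmarks of a constant image all equal the constant", {
  img <- VolumeImage(array(13.5, c(8, 8, 8)))
  lm <- computeLandmarks(img, VoxelMask(array(TRUE, c(8, 8, 8))))
  expect_true(all(landmarkIntensities(lm) == 13.5))
})

test_that("landmarks are equivariant under affine intensity maps", {
  ph <- generatePhantom(phantomSpec(), seed = 6)
  lm <- computeLandmarks(ph$image, ph$masks$tissue)
  img2 <- VolumeImage(2 * voxelData(ph$image) + 5, voxelSpacing(ph$image))
  lm2 <- computeLandmarks(img2, ph$masks$tissue)
  expect_equal(landmarkIntensities(lm2), 2 * landmarkIntensities(lm) + 5,
               tolerance = 1e-12)
})

test_that("normalizing the reference to itself is the identity within 1e-6", {
  ph <- generatePhantom(phantomSpec(), seed = 8)
  mask <- ph$masks$tissue
  lm <- computeLandmarks(ph$image, mask)
  out <- applyDecileNormalization(ph$image, mask, lm)
  x <- voxelData(ph$image)[voxelData(mask)]
  y <- voxelData(out)[voxelData(mask)]
  expect_lt(max(abs(y - x) / pmax(abs(x), 1e-12)), 1e-6)
})

test_that("affine sources land exactly on the reference landmarks at the knots", {
  ph <- generatePhantom(phantomSpec(), seed = 9)
  mask <- ph$masks$tissue
  ref <- computeLandmarks(ph$image, mask)
  src <- VolumeImage(2 * voxelData(ph$image) + 5, voxelSpacing(ph$image))
  out <- applyDecileNormalization(src, mask, ref)
  post <- computeLandmarks(out, mask)
  expect_equal(landmarkIntensities(post), landmarkIntensities(ref),
               tolerance = 1e-6)
})

test_that("non-monotone reference landmarks are rejected", {
  expect_error(new("LandmarkMap", percentiles = c(10, 50, 90),
                   intensities = c(5, 3, 9), referenceId = "x"),
               "non-decreasing")
  expect_error(new("LandmarkMap", percentiles = c(10, 90, 50),
                   intensities = c(1, 2, 3), referenceId = "x"),
               "increasing")
})

test_that("the fitted landmark map is monotone over the intensity range", {
  set.seed(123)
  for (rep in 1:100) {
    srcL <- sort(runif(11, 0, 100)) + seq(0, 1, length.out = 11)
    refL <- sort(runif(11, 0, 100))
    f <- radirep:::landmarkMapFunction(srcL, refL)
    grid <- seq(srcL[1] - 10, srcL[11] + 10, length.out = 400)
    expect_true(all(diff(f(grid)) >= -1e-9))
  }
})

test_that("normalization is idempotent against the same reference", {
  ph <- generatePhantom(phantomSpec(), seed = 10)
  mask <- ph$masks$tissue
  ref <- computeLandmarks(ph$image, mask)
  src <- VolumeImage(1.7 * voxelData(ph$image)^1.1 + 3, voxelSpacing(ph$image))
  once <- applyDecileNormalization(src, mask, ref)
  twice <- applyDecileNormalization(once, mask, ref)
  l1 <- landmarkIntensities(computeLandmarks(once, mask))
  l2 <- landmarkIntensities(computeLandmarks(twice, mask))
  expect_lt(max(abs(l2 - l1) / pmax(abs(l1), 1e-12)), 1e-6)
})

test_that("a degenerate source maps to the reference median with a warning", {
  ref <- new("LandmarkMap", percentiles = defaultLandmarkPercentiles(),
             intensities = as.numeric(1:11), referenceId = "r")
  img <- VolumeImage(array(4, c(8, 8, 8)))
  mask <- VoxelMask(array(TRUE, c(8, 8, 8)))
  expect_warning(out <- applyDecileNormalization(img, mask, ref), "degenerate")
  expect_true(all(voxelData(out) == median(1:11)))
})

test_that("normalization lowers histogram-feature CV for monotone affine pairs", {
  # the harmonization mechanism: images differing only by a monotone
  # intensity map should agree after landmark matching
  set.seed(31)
  for (rep in 1:5) {
    ph <- generatePhantom(phantomSpec(), seed = 300 + rep)
    mask <- ph$masks$tissue
    ref <- computeLandmarks(ph$image, mask)
    gain <- runif(1, 1.5, 3); off <- runif(1, 10, 40)
    src <- VolumeImage(gain * voxelData(ph$image) + off, voxelSpacing(ph$image))
    h1raw <- computeHistogramFeatures(ph$image, mask)
    h2raw <- computeHistogramFeatures(src, mask)
    nrm <- applyDecileNormalization(src, mask, ref)
    h2n <- computeHistogramFeatures(nrm, mask)
    cvRaw <- mapply(function(a, b) featureCV(c(a, b)), h1raw, h2raw)
    cvNorm <- mapply(function(a, b) featureCV(c(a, b)), h1raw, h2n)
    expect_lt(mean(cvNorm, na.rm = TRUE), mean(cvRaw, na.rm = TRUE))
  }
})

test_that("landmark maps survive a JSON round trip", {
  lm <- new("LandmarkMap", percentiles = defaultLandmarkPercentiles(),
            intensities = sort(runif(11, 0, 200)), referenceId = "sess-1")
  path <- tempfile(fileext = ".json")
  writeLandmarkJSON(lm, path)
  back <- readLandmarkJSON(path)
  expect_equal(landmarkIntensities(back), landmarkIntensities(lm))
  expect_equal(back@referenceId, "sess-1")
})
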