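# Feature catalog, histogram, shape and texture features.

test_that("the default catalog has the pinned class composition", {
  cat <- defaultFeatureCatalog()
  cnt <- table(catalogEntries(cat)$class)
  expect_equal(nrow(catalogEntries(cat)), 396L)
  expect_equal(unname(cnt[c("histogram", "form_factor", "glcm", "rlm",
                            "glszm", "cluster", "correlation")]),
               c(42L, 9L, 100L, 180L, 11L, 36L, 18L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(names(cat)) > 0)
})

test_that("the shipped registry JSON matches the in-code catalog", {
  shipped <- readCatalogJSON()
  expect_equal(catalogEntries(shipped), catalogEntries(defaultFeatureCatalog()))
})

test_that("histogram features handle constant regions and tiny samples", {
  f <- computeHistogramFeatures(rep(3.5, 50))
  expect_equal(unname(f["Mean"]), 3.5)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["HistEntropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
  f2 <- computeHistogramFeatures(c(1, 2, 3, 4))
  expect_equal(unname(f2["Median"]), 2.5)
  expect_equal(unname(f2["Range"]), 3)
})

test_that("binned histogram entropy/energy follow the 2-bin hand computation", {
  f <- computeHistogramFeatures(c(1, 1, 2, 2), nBins = 2)
  expect_equal(unname(f["HistEntropy"]), 1)   # 1 bit
  expect_equal(unname(f["HistEnergy"]), 0.5)
})

test_that("a single voxel has V=1, A=6 and zero diameter at 1 mm spacing", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  f <- computeShapeFeatures(VoxelMask(m))
  expect_equal(unname(f["Volume"]), 1)
  expect_equal(unname(f["SurfaceArea"]), 6)
  expect_equal(unname(f["Maximum3DDiameter"]), 0)
})

test_that("solid cubes have size-independent sphericity pi^(1/3)*6^(2/3)/6", {
  target <- pi^(1 / 3) * 6^(2 / 3) / 6
  for (n in c(3, 5, 8)) {
    m <- array(FALSE, c(n + 2, n + 2, n + 2))
    m[2:(n + 1), 2:(n + 1), 2:(n + 1)] <- TRUE
    f <- computeShapeFeatures(VoxelMask(m))
    expect_equal(unname(f["Sphericity"]), target, tolerance = 1e-12)
    expect_equal(unname(f["SurfaceArea"]), 6 * n^2)
  }
})

test_that("sphericity times spherical disproportion is 1 on random masks", {
  set.seed(99)
  for (rep in 1:10) {
    m <- array(runif(10 * 10 * 6) < 0.4, c(10, 10, 6))
    m[5, 5, 3] <- TRUE
    f <- computeShapeFeatures(VoxelMask(m, spacing = runif(3, 0.5, 2)))
    expect_equal(unname(f["Sphericity"] * f["SphericalDisproportion"]), 1,
                 tolerance = 1e-10)
  }
})

test_that("the 2x2 co-occurrence hand example gives P(1,1)=P(2,2)=0.5", {
  arr <- array(NA_integer_, c(2, 2, 1))
  arr[, , 1] <- matrix(c(1, 1, 2, 2), 2, byrow = TRUE)
  dv <- makeDiscrete(arr, 2)
  P <- buildGLCM(dv, "angle0", 1)
  expect_equal(P[1, 1], 0.5)
  expect_equal(P[2, 2], 0.5)
  expect_equal(P[1, 2], 0)
  fs <- radirep:::glcmFeatureSet(P)
  expect_equal(unname(fs["GLCMEnergy"]), 0.5)
  expect_equal(unname(fs["GLCMEntropy"]), 1)
})

test_that("co-occurrence matrices are symmetric and sum to one", {
  set.seed(4)
  for (rep in 1:5) {
    dv <- randomDiscreteVolume()
    for (a in c("angle0", "angle45", "angle90", "angle135", "AllDirection")) {
      P <- buildGLCM(dv, a, 1)
      if (is.null(P)) next
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P))
    }
  }
})

test_that("degenerate matrices give the documented closed forms", {
  # uniform diagonal: entropy log2(L); single cell: energy 1, entropy 0
  L <- 8
  Pdiag <- diag(rep(1 / L, L))
  fs <- radirep:::glcmFeatureSet(Pdiag)
  expect_equal(unname(fs["GLCMEntropy"]), log2(L))
  Pone <- matrix(0, 4, 4); Pone[2, 3] <- 1
  fs1 <- radirep:::glcmFeatureSet(Pone)
  expect_equal(unname(fs1["GLCMEnergy"]), 1)
  expect_equal(unname(fs1["GLCMEntropy"]), 0)
})

test_that("cluster shade vanishes for gray-level distributions symmetric about the mean", {
  # symmetric matrix with intensity distribution symmetric about its mean
  P <- matrix(0, 3, 3)
  P[1, 1] <- 0.25; P[3, 3] <- 0.25; P[1, 3] <- 0.125; P[3, 1] <- 0.125
  P[2, 2] <- 0.25
  fs <- radirep:::glcmFeatureSet(P)
  expect_equal(unname(fs["ClusterShade"]), 0, tolerance = 1e-12)
})

test_that("offsets with no valid pair yield the NaN sentinel downstream", {
  arr <- array(1L, c(3, 3, 1))
  dv <- makeDiscrete(arr, 2)
  expect_null(buildGLCM(dv, "angle0", 7))
  vals <- computeGLCMFeatures(glcmMatrices(dv, offsets = c(1L, 4L, 7L)))
  expect_true(all(is.nan(vals[grepl("offset7", names(vals))])))
  expect_false(anyNA(vals[grepl("GLCMEnergy.*offset1", names(vals))]))
})

test_that("run enumeration matches the [1,1,1,2] hand example", {
  arr <- array(NA_integer_, c(1, 4, 1))
  arr[1, , 1] <- c(1L, 1L, 1L, 2L)
  R <- buildRunLengthMatrix(makeDiscrete(arr, 2), "angle0")
  expect_equal(R[1, 3], 1)  # level 1, length 3
  expect_equal(R[2, 1], 1)  # level 2, length 1
  expect_equal(sum(R), 2)
})

test_that("a constant row has run percentage 1/n and a checkerboard SRE 1", {
  n <- 7
  arr <- array(1L, c(1, n, 1))
  dv <- makeDiscrete(arr, 1)
  R <- buildRunLengthMatrix(dv, "angle0")
  fs <- radirep:::rlmFeatureSet(R, Np = n)
  expect_equal(unname(fs["RunPercentage"]), 1 / n)
  cb <- array(0L, c(6, 6, 1))
  cb[, , 1] <- (outer(1:6, 1:6, "+") %% 2L) + 1L
  fsc <- radirep:::rlmFeatureSet(buildRunLengthMatrix(makeDiscrete(cb, 2),
                                                      "angle0"), Np = 36)
  expect_equal(unname(fsc["ShortRunEmphasis"]), 1)
})

test_that("size zones partition the VOI and follow the closed forms", {
  # constant VOI: one zone of n voxels, zone percentage 1/n
  arr <- array(1L, c(4, 4, 2))
  z <- zoneTable(makeDiscrete(arr, 1))
  expect_equal(nrow(z), 1L)
  expect_equal(z$size, 32L)
  fs <- computeGLSZMFeatures(makeDiscrete(arr, 1))
  expect_equal(unname(fs["ZonePercentage"]), 1 / 32)
  # isolated voxels: every zone has size 1, SAE = 1
  iso <- array(NA_integer_, c(4, 4, 1))
  iso[, , 1] <- matrix(rep_len(1:8, 16), 4)  # no two equal 26-neighbors
  iso[, , 1] <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 1, 2, 3, 4, 5, 6, 7, 8), 4)
  zi <- zoneTable(makeDiscrete(iso, 8))
  if (all(zi$size == 1L))
    expect_equal(unname(computeGLSZMFeatures(makeDiscrete(iso, 8))["SmallAreaEmphasis"]), 1)
  # partition property on random volumes
  set.seed(11)
  for (rep in 1:5) {
    dv <- randomDiscreteVolume()
    z <- zoneTable(dv)
    expect_equal(sum(z$size), sum(!is.na(voxelData(dv))))
  }
})

test_that("AllDirection features respect the pooled-mixture convexity bounds", {
  # AllDirection is the normalized sum (a mixture) of the per-angle
  # matrices: entropy is concave (mixture >= min per-angle, <= max +
  # log2(4) mixing bits); energy is convex (mixture <= max per-angle)
  set.seed(13)
  for (rep in 1:5) {
    dv <- randomDiscreteVolume(c(8, 8, 3), L = 5)
    mats <- glcmMatrices(dv, offsets = 1L)
    per <- function(base) vapply(c("angle0", "angle45", "angle90", "angle135"),
                                 function(a) radirep:::glcmFeatureSet(
                                   mats[[paste0(a, "_offset1")]])[base],
                                 numeric(1))
    allOf <- function(base)
      radirep:::glcmFeatureSet(mats[["AllDirection_offset1"]])[[base]]
    ent <- per("GLCMEntropy")
    expect_gte(allOf("GLCMEntropy") + 1e-9, min(ent))
    expect_lte(allOf("GLCMEntropy") - 1e-9, max(ent) + log2(4))
    expect_lte(allOf("GLCMEnergy") - 1e-9, max(per("GLCMEnergy")))
  }
})

test_that("full extraction returns exactly one value per catalog entry", {
  ph <- generatePhantom(phantomSpec(gridShape = c(24L, 24L, 12L)), seed = 14)
  fv <- extractAllFeatures(ph$image, ph$masks$tissue, levels = 32L)
  expect_length(fv, 396L)
  expect_identical(names(fv), names(defaultFeatureCatalog()))
  expect_false(anyNA(fv))
  # identical sessions give identical vectors
  fv2 <- extractAllFeatures(ph$image, ph$masks$tissue, levels = 32L)
  expect_identical(fv, fv2)
})

test_that("shape features ignore intensity transforms; texture is monotone-invariant", {
  ph <- generatePhantom(phantomSpec(gridShape = c(24L, 24L, 12L)), seed = 15)
  img2 <- VolumeImage(3 * voxelData(ph$image)^1.2 + 11, voxelSpacing(ph$image))
  f1 <- extractAllFeatures(ph$image, ph$masks$tissue, levels = 32L)
  f2 <- extractAllFeatures(img2, ph$masks$tissue, levels = 32L)
  cls <- catalogEntries(defaultFeatureCatalog())$class
  texture <- cls %in% c("glcm", "rlm", "glszm", "cluster", "correlation")
  expect_identical(f1[cls == "form_factor"], f2[cls == "form_factor"])
  expect_equal(f1[texture], f2[texture], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1[cls == "histogram"], f2[cls == "histogram"])))
})
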