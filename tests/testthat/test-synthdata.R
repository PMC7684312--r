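# Phantom generation, scanner effects and study designs.

test_that("phantom generation is deterministic and respects degenerate settings", {
  spec <- phantomSpec(layout = "kiwi")
  a <- generatePhantom(spec, seed = 11)
  b <- generatePhantom(spec, seed = 11)
  expect_identical(voxelData(a$image), voxelData(b$image))
  expect_identical(voxelData(a$masks$tissue), voxelData(b$masks$tissue))
  c <- generatePhantom(spec, seed = 12)
  expect_false(identical(voxelData(a$image), voxelData(c$image)))

  flat <- phantomSpec(layout = "kiwi", textureAmplitude = 0, noiseSigma = 0)
  ph <- generatePhantom(flat, seed = 5)
  inside <- voxelData(ph$image)[voxelData(ph$masks$tissue)]
  expect_true(all(inside == flat@tissueMeans[1]))
})

test_that("two-layer phantoms have disjoint non-empty layer masks", {
  spec <- phantomSpec(layout = "cervix", tissueMeans = c(120, 80),
                      textureCorrLength = c(2.5, 4), textureAmplitude = c(15, 12))
  ph <- generatePhantom(spec, seed = 3)
  inner <- voxelData(ph$masks$inner)
  outer <- voxelData(ph$masks$outer)
  expect_gt(sum(inner), 0)
  expect_gt(sum(outer), 0)
  expect_false(any(inner & outer))
})

test_that("degenerate phantom grids are rejected", {
  expect_error(phantomSpec(gridShape = c(6, 32, 24)), "gridShape")
  expect_error(phantomSpec(textureAmplitude = -1), "textureAmplitude")
})

test_that("identity scanner effect returns the input voxel-for-voxel", {
  ph <- generatePhantom(phantomSpec(), seed = 2)
  out <- applyScannerEffect(ph$image, scannerEffect(), seed = 9)
  expect_identical(voxelData(out), voxelData(ph$image))
})

test_that("affine intensity maps act exactly on constant volumes", {
  img <- VolumeImage(array(10, c(8, 8, 8)))
  out <- applyScannerEffect(img, scannerEffect(gain = 2, offset = 5), seed = 1)
  expect_true(all(voxelData(out) == 25))
})

test_that("Rician noise is reproducible under a fixed seed", {
  ph <- generatePhantom(phantomSpec(), seed = 2)
  eff <- scannerEffect(ricianSigma = 3)
  a <- applyScannerEffect(ph$image, eff, seed = 77)
  b <- applyScannerEffect(ph$image, eff, seed = 77)
  c <- applyScannerEffect(ph$image, eff, seed = 78)
  expect_identical(voxelData(a), voxelData(b))
  expect_false(identical(voxelData(a), voxelData(c)))
})

test_that("monotone gain/offset/gamma effects preserve voxel rank order", {
  ph <- generatePhantom(phantomSpec(), seed = 4)
  m <- voxelData(ph$masks$tissue)
  for (eff in list(scannerEffect(gain = 3.2, offset = -4),
                   scannerEffect(gamma = 1.3),
                   scannerEffect(gain = 0.4, offset = 12, gamma = 0.8))) {
    out <- applyScannerEffect(ph$image, eff, seed = 1)
    expect_identical(order(voxelData(out)[m]), order(voxelData(ph$image)[m]))
  }
})

test_that("non-monotone scanner parameters are rejected", {
  expect_error(scannerEffect(gain = -1), "gain")
  expect_error(scannerEffect(gamma = 0), "gamma")
  img <- VolumeImage(array(c(-5, seq_len(7 * 8 * 8 - 1)), c(7, 8, 8)))
  expect_error(applyScannerEffect(img, scannerEffect(gamma = 2), seed = 1),
               "non-negative")
})

test_that("study designs enumerate exactly one session per (subject, condition)", {
  dflt <- defaultParameterSweeps()
  design <- studyDesign(nKiwi = 1L, nVolunteer = 2L,
                        sweeps = dflt$sweeps["TE"], sweepLabels = dflt$labels["TE"],
                        masterSeed = 99L)
  study <- generateStudy(design)
  man <- study$manifest
  expect_equal(sum(man$arm == "inter"), 3 * 3)   # 3 subjects x 3 scanners
  expect_equal(sum(man$arm == "intra"), 3 * 4)   # 3 subjects x 4 TE levels
  expect_false(anyDuplicated(man$session_id) > 0)
  # TE sweep varies TE only; nominal TR/ST/AM are held fixed
  intra <- man[man$arm == "intra", ]
  expect_setequal(unique(intra$TE), c(80, 90, 100, 110))
  expect_equal(unique(intra$TR), 3000)
})

test_that("the intra arm of a 4-level sweep over 9 subjects has 36 sessions", {
  dflt <- defaultParameterSweeps()
  design <- studyDesign(nKiwi = 0L, nVolunteer = 9L,
                        sweeps = dflt$sweeps["TE"], sweepLabels = dflt$labels["TE"],
                        masterSeed = 1L)
  man <- generateStudy(design)$manifest
  expect_equal(sum(man$arm == "intra"), 36L)
})

test_that("identical master seeds reproduce the whole study", {
  design <- studyDesign(nKiwi = 1L, nVolunteer = 1L, masterSeed = 7L)
  s1 <- generateStudy(design)
  s2 <- generateStudy(design)
  expect_identical(s1$manifest, s2$manifest)
  id <- s1$manifest$session_id[5]
  expect_identical(voxelData(s1$sessions[[id]]$image),
                   voxelData(s2$sessions[[id]]$image))
})

test_that("a subject keeps the same underlying phantom across its sessions", {
  design <- studyDesign(nKiwi = 1L, nVolunteer = 0L, masterSeed = 21L)
  study <- generateStudy(design)
  # the PH scanner applies no intensity map, only Rician noise: sessions of
  # the same subject should correlate far more than independent phantoms
  a <- voxelData(study$sessions[["K1_inter_PH"]]$image)
  b <- voxelData(study$sessions[["K1_inter_GE"]]$image)
  expect_gt(cor(as.numeric(a), as.numeric(b)), 0.9)
})

test_that("empty sweeps are rejected", {
  expect_error(studyDesign(sweeps = list(TE = list()), sweepLabels = list(TE = numeric())),
               "empty")
})
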