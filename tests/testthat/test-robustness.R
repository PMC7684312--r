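# CV/QCD statistics and reproducibility screening.

test_that("CV follows the sample-sd-over-mean definition with |.| convention", {
  expect_equal(featureCV(c(5, 5, 5)), 0)
  expect_equal(featureCV(c(8, 10, 12)), 0.2)
  expect_equal(featureCV(c(-8, -10, -12)), 0.2)
  expect_true(is.na(featureCV(c(-1, 1))))       # zero mean, nonzero sd
  expect_equal(featureCV(c(0, 0, 0)), 0)        # constant at zero
  expect_error(featureCV(5), "at least 2")
})

test_that("QCD follows the linear-interpolation quartile convention", {
  expect_equal(featureQCD(c(7, 7, 7, 7)), 0)
  expect_equal(featureQCD(c(10, 20, 30, 40)), 30)  # Q1=17.5, Q3=32.5
  expect_true(is.na(featureQCD(c(-10, 0, 10))))    # Q3+Q1 = 0
  expect_error(featureQCD(c(1, 2)), "at least 3")
})

test_that("CV and QCD are exactly scale-invariant under k > 0", {
  set.seed(5)
  for (rep in 1:1000) {
    v <- rnorm(sample(3:8, 1), mean = runif(1, 1, 50), sd = runif(1, 0, 5))
    k <- runif(1, 0.01, 100)
    cv <- featureCV(v); qcd <- featureQCD(v)
    if (is.na(cv) || is.na(qcd)) next
    expect_equal(featureCV(k * v), cv, tolerance = 1e-12)
    expect_equal(featureQCD(k * v), qcd, tolerance = 1e-9)
  }
})

# small synthetic feature table: 2 groups x 2 subjects x 3 sessions
makeFeatureTable <- function(valueFun) {
  rows <- list()
  for (g in c("G.0", "G.1")) for (s in 1:2) for (k in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      session_id = sprintf("%s_S%d_%d", g, s, k),
      subject = sprintf("%s_S%d", g, s), group = g, arm = "inter",
      featA = valueFun(g, s, k, "A"), featB = valueFun(g, s, k, "B"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("identical sessions pass every cutoff for every feature", {
  tab <- makeFeatureTable(function(g, s, k, f) if (f == "A") 10 else -3)
  scr <- screenFeatures(tab)
  expect_true(all(scr$records$meanCV == 0))
  expect_true(all(scr$counts$count == 2L))
  expect_true(all(scr$counts$pct == 100))
})

test_that("looser cutoffs pass a superset of stricter cutoffs", {
  set.seed(8)
  tab <- makeFeatureTable(function(g, s, k, f) rnorm(1, 100, 12))
  scr <- screenFeatures(tab)
  for (g in c("G.0", "G.1")) {
    expect_true(all(scr$passSets[[paste0(g, "|CV<0.1")]] %in%
                    scr$passSets[[paste0(g, "|CV<0.15")]]))
    expect_true(all(scr$passSets[[paste0(g, "|QCD<10")]] %in%
                    scr$passSets[[paste0(g, "|QCD<15")]]))
  }
})

test_that("sentinel-bearing features are treated as non-reproducible", {
  tab <- makeFeatureTable(function(g, s, k, f)
    if (f == "A") c(-1, 0, 1)[k] else 10)  # feature A: zero-mean, nonzero sd
  scr <- screenFeatures(tab)
  recA <- scr$records[scr$records$feature == "featA", ]
  expect_true(all(is.na(recA$meanCV)))
  expect_false("featA" %in% scr$passSets[["G.0|CV<0.15"]])
  expect_true("featB" %in% scr$passSets[["G.0|CV<0.1"]])
})

test_that("gain differences break intensity features but never shape features", {
  # inter-scanner study with strong gain/offset differences, no normalization
  design <- studyDesign(nKiwi = 2L, nVolunteer = 0L, sweeps = list(),
                        sweepLabels = list(), masterSeed = 404L)
  study <- generateStudy(design)
  tab <- extractStudyFeatures(study$sessions, levels = 64L)
  scr <- screenFeatures(tab)
  rec <- scr$records
  cls <- catalogEntries(defaultFeatureCatalog())
  shapeFeats <- cls$name[cls$class == "form_factor"]
  pass01 <- scr$passSets[["G.0|CV<0.1"]]
  expect_true(all(shapeFeats %in% pass01))
  expect_false("Mean" %in% pass01)
  expect_false("Median" %in% pass01)
})

test_that("shared reproducible features are the across-group intersection", {
  one <- sharedReproducible(list(g1 = c("a", "b", "c")))
  expect_equal(one$features, c("a", "b", "c"))
  none <- sharedReproducible(list(g1 = c("a"), g2 = c("b")))
  expect_equal(none$count, 0L)
  some <- sharedReproducible(list(g1 = c("a", "b", "c"), g2 = c("b", "c"),
                                  g3 = c("c", "b", "x")), catalogSize = 396L)
  expect_setequal(some$features, c("b", "c"))
  expect_equal(some$fraction, 2 / 396)
  expect_lte(some$count, min(3, 2, 3))
})

test_that("high/low parameter-level comparison behaves at its edge cases", {
  cv <- runif(50, 0, 0.3)
  same <- compareParameterLevels(cv, cv)
  expect_equal(same$p.value, 1)
  shifted <- compareParameterLevels(cv + 5, cv)
  expect_lt(shifted$p.value, 0.05)
  swapped <- compareParameterLevels(cv, cv + 5)
  expect_equal(shifted$p.value, swapped$p.value, tolerance = 1e-12)
})
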