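# Five-step filtering, hierarchical clustering, representative picking.

recOf <- function(features, cv, qcd = 1, group = "G.0") {
  data.frame(group = group, feature = features, meanCV = cv,
             meanQCD = rep_len(qcd, length(features)), stringsAsFactors = FALSE)
}

test_that("all-pass records survive all four steps", {
  feats <- paste0("f", 1:10)
  rec <- recOf(feats, cv = 0.01)
  flt <- fiveStepFilter(rec, rec, rec, rec)
  expect_setequal(flt$survivors, feats)
  expect_true(is.na(flt$emptiedAt))
})

test_that("a feature failing only step 2 is absent from steps 3-4", {
  feats <- paste0("f", 1:5)
  ok <- recOf(feats, cv = 0.01)
  bad2 <- recOf(feats, cv = c(0.01, 0.5, 0.01, 0.01, 0.01))
  flt <- fiveStepFilter(ok, bad2, ok, ok)
  expect_false("f2" %in% flt$steps$step2)
  expect_false("f2" %in% flt$steps$step3)
  expect_false("f2" %in% flt$steps$step4)
  expect_setequal(flt$survivors, setdiff(feats, "f2"))
})

test_that("survivor counts are non-increasing across steps", {
  set.seed(17)
  feats <- paste0("f", 1:40)
  mk <- function() recOf(feats, cv = runif(40, 0, 0.2), qcd = runif(40, 0, 20))
  flt <- fiveStepFilter(mk(), mk(), mk(), mk())
  n <- vapply(flt$steps, length, integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("a multi-group record set requires passing in every group", {
  feats <- c("a", "b")
  rec <- rbind(recOf(feats, cv = c(0.01, 0.01), group = "G.1"),
               recOf(feats, cv = c(0.01, 0.5), group = "G.2"))
  flt <- fiveStepFilter(recOf(feats, 0.01), recOf(feats, 0.01), rec,
                        recOf(feats, 0.01))
  expect_equal(flt$survivors, "a")
})

test_that("perfectly correlated features cluster together", {
  set.seed(20)
  x <- rnorm(30)
  fm <- cbind(f1 = x, f2 = 3 * x + 2, f3 = rnorm(30))
  cl <- clusterFeatures(fm, k = 2)
  expect_equal(cl$assignment[["f1"]], cl$assignment[["f2"]])
  expect_false(cl$assignment[["f1"]] == cl$assignment[["f3"]])
})

test_that("k = number of survivors gives singleton clusters", {
  set.seed(21)
  fm <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  cl <- clusterFeatures(fm, k = 4)
  expect_equal(as.integer(sort(table(cl$assignment))), rep(1L, 4))
})

test_that("constant features are dropped with a warning before clustering", {
  set.seed(22)
  fm <- cbind(f1 = rnorm(20), f2 = rnorm(20), f3 = rep(5, 20))
  expect_warning(cl <- clusterFeatures(fm, k = 2), "constant")
  expect_false("f3" %in% names(cl$assignment))
})

test_that("representatives take the cluster minimum CV with catalog-order ties", {
  clustering <- list(assignment = c(A = 1L, B = 1L, C = 2L, D = 2L, E = 2L))
  cv <- c(A = 0.05, B = 0.08, C = 0.07, D = 0.07, E = 0.02)
  reps <- pickRepresentatives(clustering, cv, catalogOrder = c("A", "B", "C", "D", "E"))
  expect_equal(reps$feature[reps$cluster == 1], "A")
  expect_equal(reps$feature[reps$cluster == 2], "E")
  # tie: D vs C both 0.07 -> earlier catalog entry C wins
  reps2 <- pickRepresentatives(list(assignment = c(C = 1L, D = 1L)),
                               c(C = 0.07, D = 0.07),
                               catalogOrder = c("A", "B", "C", "D", "E"))
  expect_equal(reps2$feature, "C")
  # singleton cluster picks its only member
  reps3 <- pickRepresentatives(list(assignment = c(B = 1L)), c(B = 0.2),
                               catalogOrder = c("A", "B"))
  expect_equal(reps3$feature, "B")
})

test_that("clustering recovers planted redundant feature groups", {
  skip_if_not_installed("mclust")
  set.seed(23)
  agreements <- vapply(1:5, function(rep) {
    nObs <- 40
    kTrue <- 5
    latent <- matrix(rnorm(nObs * kTrue), nObs)
    truth <- integer(0)
    cols <- list()
    for (g in seq_len(kTrue)) for (j in 1:4) {
      f <- function(x) x  # monotone variants of the latent signal
      v <- switch(j, latent[, g], 2 * latent[, g] + 1, latent[, g]^3,
                  tanh(latent[, g]))
      cols[[length(cols) + 1L]] <- v + rnorm(nObs, sd = 0.01)
      truth <- c(truth, g)
    }
    fm <- do.call(cbind, cols)
    colnames(fm) <- paste0("f", seq_along(truth))
    cl <- clusterFeatures(fm, k = kTrue)
    mclust::adjustedRandIndex(unname(cl$assignment), truth)
  }, numeric(1))
  expect_true(all(agreements > 0.9))
})

test_that("clustering is deterministic for fixed inputs", {
  set.seed(24)
  fm <- matrix(rnorm(25 * 6), 25, dimnames = list(NULL, paste0("f", 1:6)))
  a <- clusterFeatures(fm, k = 3)
  b <- clusterFeatures(fm, k = 3)
  expect_identical(a$assignment, b$assignment)
})
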