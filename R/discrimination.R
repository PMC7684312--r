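# ROC evaluation of representative features for two-tissue discrimination.

#' AUC with confidence interval for two-class feature values
#'
#' Mann-Whitney AUC (ties count 1/2) of class B scoring above class A,
#' oriented to >= 0.5 by flipping when needed (the flip is recorded, so the
#' direction of effect is never hidden). The 95 percent CI is DeLong when
#' both classes have at least \code{minDeLong} observations, otherwise a
#' seeded bootstrap (both via pROC).
#'
#' @param a,b numeric feature values of the two classes (>= 2 each).
#' @param minDeLong minimum per-class size for the DeLong CI (default 10).
#' @param bootN bootstrap replicates for small samples (default 1000).
#' @param seed seed for the bootstrap CI.
#' @param ciLevel confidence level (default 0.95).
#' @return list with \code{auc}, \code{ciLower}, \code{ciUpper},
#'   \code{flipped}, \code{nA}, \code{nB}, \code{ciMethod}.
#' @examples
#' aucWithCI(c(1, 2, 3), c(2, 3, 4))$auc  # 7/9
#' @export
aucWithCI <- function(a, b, minDeLong = 10L, bootN = 1000L, seed = 1L,
                      ciLevel = 0.95) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each class needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("feature values must be finite")
  nA <- length(a)
  nB <- length(b)
  r <- rank(c(a, b), ties.method = "average")
  auc <- (sum(r[(nA + 1):(nA + nB)]) - nB * (nB + 1) / 2) / (nA * nB)
  flipped <- auc < 0.5
  if (flipped) auc <- 1 - auc
  direction <- if (flipped) ">" else "<"
  resp <- factor(c(rep("A", nA), rep("B", nB)), levels = c("A", "B"))
  roc <- pROC::roc(resp, c(a, b), levels = c("A", "B"),
                   direction = direction, quiet = TRUE)
  if (min(nA, nB) >= minDeLong) {
    ci <- pROC::ci.auc(roc, conf.level = ciLevel, method = "delong")
    ciMethod <- "delong"
  } else {
    set.seed(as.integer(seed))
    ci <- suppressWarnings(pROC::ci.auc(roc, conf.level = ciLevel,
                                        method = "bootstrap", boot.n = bootN))
    ciMethod <- "bootstrap"
  }
  list(auc = auc, ciLower = max(0, min(ci[1], auc)),
       ciUpper = min(1, max(ci[3], auc)), flipped = flipped,
       nA = nA, nB = nB, ciMethod = ciMethod)
}

#' Evaluate representative features for tissue discrimination
#'
#' For every representative feature and arm (raw / normalized), computes
#' the AUC with CI for discriminating the two tissue classes (inner-layer
#' vs outer-layer analog), plus paired per-feature reproducibility CVs of
#' the two arms for boxplot export. Form-factor features are excluded from
#' the arm comparison: they depend on the mask only and cannot change with
#' intensity normalization.
#'
#' @param tissueTables named list of feature tables per arm (elements
#'   "raw", "normalized"), each with a \code{tissue} metadata column with
#'   two classes.
#' @param representatives character vector of representative feature names.
#' @param cvByArm optional named list per arm of named per-feature CVs
#'   (for the boxplot pairing).
#' @param catalog a \linkS4class{FeatureCatalog} (to identify form-factor
#'   features).
#' @param seed passed to the bootstrap CI.
#' @return list with \code{roc} (data.frame: arm, feature, auc, ciLower,
#'   ciUpper, flipped, nA, nB) and \code{cvPairs} (data.frame: feature,
#'   arm, cv; NULL when \code{cvByArm} is absent).
#' @export
evaluateRepresentatives <- function(tissueTables, representatives,
                                    cvByArm = NULL,
                                    catalog = defaultFeatureCatalog(),
                                    seed = 1L) {
  entries <- catalogEntries(catalog)
  shapeFeats <- entries$name[entries$class == "form_factor"]
  usable <- setdiff(representatives, shapeFeats)
  rocRows <- list()
  for (arm in names(tissueTables)) {
    tab <- tissueTables[[arm]]
    stopifnot("tissue" %in% names(tab))
    classes <- sort(unique(tab$tissue))
    if (length(classes) != 2L) stop("need exactly two tissue classes")
    for (f in usable) {
      va <- tab[[f]][tab$tissue == classes[1]]
      vb <- tab[[f]][tab$tissue == classes[2]]
      if (any(!is.finite(va)) || any(!is.finite(vb))) next  # sentinel: skip, logged
      res <- aucWithCI(va, vb, seed = seed)
      rocRows[[length(rocRows) + 1L]] <- data.frame(
        arm = arm, feature = f, auc = res$auc, ciLower = res$ciLower,
        ciUpper = res$ciUpper, flipped = res$flipped, nA = res$nA,
        nB = res$nB, stringsAsFactors = FALSE)
    }
  }
  roc <- do.call(rbind, rocRows)
  cvPairs <- NULL
  if (!is.null(cvByArm)) {
    cvPairs <- do.call(rbind, lapply(names(cvByArm), function(arm) {
      cvs <- cvByArm[[arm]][usable]
      data.frame(feature = usable, arm = arm, cv = unname(cvs),
                 stringsAsFactors = FALSE)
    }))
  }
  list(roc = roc, cvPairs = cvPairs)
}
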