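# Representative robust feature selection: sequential reproducibility
# filtering followed by hierarchical clustering of the survivors and
# lowest-CV representative picking per cluster.

passSet <- function(records, cvCutoff, qcdCutoff, within = NULL) {
  stopifnot(all(c("feature", "meanCV", "meanQCD") %in% names(records)))
  ok <- is.finite(records$meanCV) & records$meanCV < cvCutoff &
    is.finite(records$meanQCD) & records$meanQCD < qcdCutoff
  feats <- unique(records$feature)
  # a feature passes when every row referring to it passes (all groups)
  passed <- vapply(feats, function(f) all(ok[records$feature == f]), logical(1))
  out <- feats[passed]
  if (!is.null(within)) out <- intersect(within, out)
  out
}

#' Five-step selection of reproducible features
#'
#' Sequential filtering at CV < cvCutoff and QCD < qcdCutoff:
#' (1) phantom inter-scanner records, (2) phantom intra-scanner records,
#' (3) volunteer inter-scanner records on the survivors,
#' (4) volunteer intra-scanner records on the survivors. The fifth step —
#' clustering and representative picking — is
#' \code{\link{clusterFeatures}} + \code{\link{pickRepresentatives}}.
#' Survivor sets are returned per step for audit and are nested by
#' construction. A feature must pass in every group present in a record
#' set; sentinel (NA) indexes fail.
#'
#' @param kiwiInter,kiwiIntra,volInter,volIntra reproducibility record
#'   data.frames (columns feature, meanCV, meanQCD; e.g. the
#'   \code{records} element of \code{\link{screenFeatures}}).
#' @param cvCutoff CV cutoff (default 0.1).
#' @param qcdCutoff QCD cutoff (default 10).
#' @return list with \code{steps} (list of 4 character vectors),
#'   \code{survivors} (the step-4 set) and, when a step empties the set,
#'   \code{emptiedAt} (the step number).
#' @export
fiveStepFilter <- function(kiwiInter, kiwiIntra, volInter, volIntra,
                           cvCutoff = 0.1, qcdCutoff = 10) {
  s1 <- passSet(kiwiInter, cvCutoff, qcdCutoff)
  s2 <- passSet(kiwiIntra, cvCutoff, qcdCutoff, within = s1)
  s3 <- passSet(volInter, cvCutoff, qcdCutoff, within = s2)
  s4 <- passSet(volIntra, cvCutoff, qcdCutoff, within = s3)
  steps <- list(step1 = s1, step2 = s2, step3 = s3, step4 = s4)
  emptiedAt <- which(vapply(steps, length, integer(1)) == 0L)
  list(steps = steps, survivors = s4,
       emptiedAt = if (length(emptiedAt)) min(emptiedAt) else NA_integer_)
}

#' Hierarchically cluster surviving features
#'
#' Agglomerative clustering of features on the dissimilarity
#' 1 - |Spearman correlation| of their value profiles across sessions,
#' complete linkage, cut into k clusters. Constant feature columns are
#' dropped with a warning before the correlation. Fully deterministic.
#'
#' @param featureMatrix numeric matrix, sessions x features (columns
#'   restricted to the survivors).
#' @param k number of clusters (capped at the number of usable features).
#' @param method linkage method for \code{\link[stats]{hclust}} (default
#'   "complete").
#' @return list with \code{assignment} (named integer vector feature ->
#'   cluster), \code{k}, \code{hclust} (the tree), \code{dropped}
#'   (constant features removed).
#' @export
clusterFeatures <- function(featureMatrix, k, method = "complete") {
  stopifnot(is.matrix(featureMatrix), ncol(featureMatrix) >= 2L,
            nrow(featureMatrix) >= 3L)
  sds <- apply(featureMatrix, 2, stats::sd)
  dropped <- colnames(featureMatrix)[!is.finite(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping constant/degenerate features before clustering: ",
            paste(dropped, collapse = ", "))
    featureMatrix <- featureMatrix[, setdiff(colnames(featureMatrix), dropped),
                                   drop = FALSE]
  }
  if (ncol(featureMatrix) < 2L) stop("fewer than 2 usable features to cluster")
  rho <- stats::cor(featureMatrix, method = "spearman")
  d <- stats::as.dist(1 - abs(rho))
  hc <- stats::hclust(d, method = method)
  k <- min(as.integer(k), ncol(featureMatrix))
  assignment <- stats::cutree(hc, k = k)
  list(assignment = assignment, k = k, hclust = hc, dropped = dropped)
}

#' Pick the lowest-CV representative of each cluster
#'
#' Within every cluster the feature with the lowest volunteer inter-scanner
#' CV is the representative robust feature; ties break deterministically by
#' catalog order. Features with a missing CV are ineligible.
#'
#' @param clustering result of \code{\link{clusterFeatures}}.
#' @param volunteerCV named numeric: volunteer inter-scanner mean CV per
#'   feature.
#' @param catalogOrder character vector fixing the tie-break order (default:
#'   the default catalog's order).
#' @return data.frame with columns cluster, feature, cv.
#' @export
pickRepresentatives <- function(clustering, volunteerCV,
                                catalogOrder = names(defaultFeatureCatalog())) {
  assignment <- clustering$assignment
  feats <- names(assignment)
  ord <- order(match(feats, catalogOrder))
  feats <- feats[ord]
  assignment <- assignment[ord]
  rows <- lapply(sort(unique(assignment)), function(cl) {
    members <- feats[assignment == cl]
    cvs <- volunteerCV[members]
    eligible <- members[is.finite(cvs)]
    if (!length(eligible)) {
      warning("cluster ", cl, " has no member with a finite CV; skipped")
      return(NULL)
    }
    best <- eligible[which.min(cvs[eligible])]  # first minimum = catalog order
    data.frame(cluster = cl, feature = best, cv = unname(cvs[best]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
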