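# Per-feature reproducibility statistics across repeated sessions.
#
# The primary index is the coefficient of variation CV = sigma / mu (sample
# standard deviation over mean, reported as an absolute value since
# features such as skewness or cluster shade can be negative); the
# supplementary index is the quartile coefficient of dispersion
# QCD = (Q3 - Q1) / (Q3 + Q1) * 100 with linear-interpolation quartiles.
# Cutoffs 0.1 / 0.15 (CV) and 10 / 15 (QCD) flag reproducible features.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' returned as an absolute value. A constant vector has CV 0 regardless of
#' its mean; a non-constant vector with zero mean is undefined and returns
#' the NA sentinel (the feature is then treated as non-reproducible). Any
#' non-finite input value also yields the sentinel.
#'
#' @param values numeric vector, length >= 2.
#' @return non-negative scalar, or NA.
#' @examples
#' featureCV(c(8, 10, 12))  # 0.2
#' @export
featureCV <- function(values) {
  if (length(values) < 2L) stop("CV needs at least 2 values")
  if (any(!is.finite(values))) return(NA_real_)
  s <- stats::sd(values)
  if (s == 0) return(0)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  abs(s / m)
}

#' Quartile coefficient of dispersion
#'
#' \eqn{(Q_3 - Q_1) / (Q_3 + Q_1) \times 100} with quartiles by linear
#' interpolation between order statistics (R quantile type 7). Q1 = Q3
#' yields 0; Q3 + Q1 = 0 with Q3 > Q1 is undefined and returns the NA
#' sentinel. Scale-invariant under multiplication by any k > 0.
#'
#' @param values numeric vector, length >= 3.
#' @return scalar (dimensionless, x100), or NA.
#' @examples
#' featureQCD(c(10, 20, 30, 40))  # 30
#' @export
featureQCD <- function(values) {
  if (length(values) < 3L) stop("QCD needs at least 3 values")
  if (any(!is.finite(values))) return(NA_real_)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(0)
  if (q[1] + q[2] == 0) return(NA_real_)
  (iqr / (q[2] + q[1])) * 100
}

#' Screen feature reproducibility across repeated sessions
#'
#' CV and QCD are computed per subject across that subject's repeated
#' sessions, then aggregated as the mean across the subjects of each group
#' (the "means within each group" reading); a feature passes a group at a
#' cutoff when its aggregated index is strictly below the cutoff. The
#' pooled variant computes each index once over all of a group's sessions.
#' Features whose index is the NA sentinel in any subject fail every
#' cutoff. QCD needs >= 3 sessions per subject and is NA otherwise.
#'
#' @param featureTable data.frame from \code{\link{extractStudyFeatures}}
#'   (metadata columns + feature columns).
#' @param cvCutoffs CV cutoffs (default 0.1, 0.15).
#' @param qcdCutoffs QCD cutoffs (default 10, 15).
#' @param pooled use the pooled-across-subjects variant (default FALSE).
#' @return list with
#'   \code{records}: per (group, feature) data.frame with meanCV, meanQCD
#'     and logical pass columns per cutoff;
#'   \code{counts}: Table-1-style data.frame (group x index x cutoff ->
#'     count, pct);
#'   \code{summary}: per group, mean and SD over features of the mean CV
#'     and mean QCD (finite values only);
#'   \code{passSets}: named list of pass-set character vectors keyed
#'     "group|index<cutoff".
#' @export
screenFeatures <- function(featureTable, cvCutoffs = c(0.1, 0.15),
                           qcdCutoffs = c(10, 15), pooled = FALSE) {
  st <- splitFeatureTable(featureTable)
  info <- st$info
  vals <- st$values
  groups <- unique(info$group)
  features <- colnames(vals)
  nFeat <- length(features)
  recs <- list()
  for (g in groups) {
    inG <- info$group == g
    subj <- unique(info$subject[inG])
    cvMat <- matrix(NA_real_, length(subj), nFeat)
    qcdMat <- matrix(NA_real_, length(subj), nFeat)
    for (si in seq_along(subj)) {
      rowsS <- inG & info$subject == subj[si]
      if (sum(rowsS) < 2L)
        stop("subject ", subj[si], " has fewer than 2 sessions")
      v <- vals[rowsS, , drop = FALSE]
      cvMat[si, ] <- apply(v, 2, featureCV)
      qcdMat[si, ] <- if (sum(rowsS) >= 3L) apply(v, 2, featureQCD) else NA_real_
    }
    if (pooled) {
      v <- vals[inG, , drop = FALSE]
      meanCV <- apply(v, 2, featureCV)
      meanQCD <- if (sum(inG) >= 3L) apply(v, 2, featureQCD) else rep(NA_real_, nFeat)
    } else {
      # mean across subjects; any sentinel makes the aggregate a sentinel
      meanCV <- colMeans(cvMat)
      meanQCD <- colMeans(qcdMat)
    }
    rec <- data.frame(group = g, feature = features, meanCV = meanCV,
                      meanQCD = meanQCD, stringsAsFactors = FALSE)
    for (ct in cvCutoffs)
      rec[[sprintf("passCV%g", ct)]] <- !is.na(meanCV) & meanCV < ct
    for (ct in qcdCutoffs)
      rec[[sprintf("passQCD%g", ct)]] <- !is.na(meanQCD) & meanQCD < ct
    recs[[g]] <- rec
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  counts <- list()
  passSets <- list()
  for (g in groups) {
    rec <- recs[[g]]
    for (ct in cvCutoffs) {
      pass <- rec$feature[rec[[sprintf("passCV%g", ct)]]]
      passSets[[sprintf("%s|CV<%g", g, ct)]] <- pass
      counts[[length(counts) + 1L]] <- data.frame(
        group = g, index = "CV", cutoff = ct, count = length(pass),
        pct = round(100 * length(pass) / nFeat, 1))
    }
    for (ct in qcdCutoffs) {
      pass <- rec$feature[rec[[sprintf("passQCD%g", ct)]]]
      passSets[[sprintf("%s|QCD<%g", g, ct)]] <- pass
      counts[[length(counts) + 1L]] <- data.frame(
        group = g, index = "QCD", cutoff = ct, count = length(pass),
        pct = round(100 * length(pass) / nFeat, 1))
    }
  }
  summary <- do.call(rbind, lapply(groups, function(g) {
    rec <- recs[[g]]
    data.frame(group = g,
               meanCV = mean(rec$meanCV[is.finite(rec$meanCV)]),
               sdCV = stats::sd(rec$meanCV[is.finite(rec$meanCV)]),
               meanQCD = mean(rec$meanQCD[is.finite(rec$meanQCD)]),
               sdQCD = stats::sd(rec$meanQCD[is.finite(rec$meanQCD)]))
  }))
  list(records = records, counts = do.call(rbind, counts),
       summary = summary, passSets = passSets)
}

#' Features reproducible in every group
#'
#' Set intersection of per-group pass sets, reported with its size and the
#' fraction of the catalog.
#'
#' @param passSets list of character vectors (one per group).
#' @param catalogSize denominator for the fraction (default 396).
#' @return list with \code{features}, \code{count}, \code{fraction}.
#' @export
sharedReproducible <- function(passSets, catalogSize = 396L) {
  stopifnot(length(passSets) >= 1L)
  shared <- Reduce(intersect, passSets)
  list(features = shared, count = length(shared),
       fraction = length(shared) / catalogSize)
}

#' Compare mean CVs between high and low parameter levels
#'
#' Two-sample two-sided t-test on per-feature mean CVs of the higher-value
#' versus lower-value halves of an acquisition-parameter sweep. Identical
#' vectors (zero difference) return p = 1 by convention; zero variance in
#' both groups with different means returns the degenerate-test sentinel
#' (NA statistic, p = NA).
#'
#' @param cvHigh,cvLow numeric vectors of per-feature mean CVs (sentinels
#'   dropped pairwise).
#' @return list with \code{statistic}, \code{p.value}, \code{meanHigh},
#'   \code{meanLow}.
#' @export
compareParameterLevels <- function(cvHigh, cvLow) {
  ok <- is.finite(cvHigh) & is.finite(cvLow)
  h <- cvHigh[ok]
  l <- cvLow[ok]
  if (!length(h) || !length(l)) stop("no finite CV values to compare")
  if (isTRUE(all.equal(h, l)) || (stats::sd(h) == 0 && stats::sd(l) == 0)) {
    if (mean(h) == mean(l))
      return(list(statistic = 0, p.value = 1, meanHigh = mean(h),
                  meanLow = mean(l)))
    return(list(statistic = NA_real_, p.value = NA_real_, meanHigh = mean(h),
                meanLow = mean(l)))
  }
  tt <- stats::t.test(h, l, alternative = "two.sided")
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       meanHigh = mean(h), meanLow = mean(l))
}
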