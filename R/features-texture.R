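# Texture matrices and their features: gray-level co-occurrence (GLCM),
# run-length (RLM) and size-zone (GLSZM).
#
# Matrices are computed in-plane (axial slices) at the four angles 0, 45,
# 90, 135 degrees and accumulated over slices; AllDirection is the
# element-wise sum of the four per-angle count matrices before
# normalization. Only in-mask voxels (non-NA levels) contribute; runs and
# pairs break at the mask boundary. Gray-level indexing is 1-based and all
# entropies use log base 2 with 0*log(0) = 0.

# displacement (di, dj) of an angle at offset d; axes are (row, column)
angleDisplacement <- function(angle, d) {
  switch(angle,
    angle0   = c(0L, d),
    angle90  = c(d, 0L),
    angle45  = c(d, d),
    angle135 = c(d, -d),
    stop("unknown angle: ", angle))
}

# Unnormalized symmetric co-occurrence counts (length L^2 vector).
glcmCounts <- function(lev, L, angle, offset) {
  d <- dim(lev)
  disp <- angleDisplacement(angle, as.integer(offset))
  counts <- numeric(L * L)
  iLo <- max(1L, 1L - disp[1]); iHi <- min(d[1], d[1] - disp[1])
  jLo <- max(1L, 1L - disp[2]); jHi <- min(d[2], d[2] - disp[2])
  if (iLo > iHi || jLo > jHi) return(counts)
  i1 <- iLo:iHi
  j1 <- jLo:jHi
  for (k in seq_len(d[3])) {
    m <- array(lev[, , k], d[1:2])
    a <- m[i1, j1, drop = FALSE]
    b <- m[i1 + disp[1], j1 + disp[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * L + b[ok]
    counts <- counts + tabulate(idx, nbins = L * L)
  }
  mat <- matrix(counts, L, L, byrow = TRUE)  # idx = (a-1)*L + b => row a, col b
  mat <- mat + t(mat)                        # symmetric pairs
  as.numeric(mat)
}

#' Build a normalized gray-level co-occurrence matrix
#'
#' Symmetric co-occurrence of in-mask gray-level pairs at the given
#' in-plane displacement, accumulated across axial slices and normalized to
#' sum 1. \code{angle = "AllDirection"} sums the four per-angle count
#' matrices before normalization. A VOI with no valid pair at the offset
#' yields the empty-matrix sentinel \code{NULL}.
#'
#' @param vol a \linkS4class{DiscreteVolume}.
#' @param angle one of "angle0", "angle45", "angle90", "angle135",
#'   "AllDirection".
#' @param offset displacement in voxels (1, 4, 7, ...).
#' @return an L x L matrix summing to 1, or NULL.
#' @export
buildGLCM <- function(vol, angle, offset) {
  stopifnot(is(vol, "DiscreteVolume"))
  L <- nGrayLevels(vol)
  lev <- voxelData(vol)
  counts <- if (angle == "AllDirection") {
    Reduce(`+`, lapply(textureAngles(), function(a) glcmCounts(lev, L, a, offset)))
  } else {
    glcmCounts(lev, L, angle, offset)
  }
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  matrix(counts / tot, L, L)
}

#' All co-occurrence matrices of a volume
#'
#' @param vol a \linkS4class{DiscreteVolume}.
#' @param offsets integer offsets (default 1, 4, 7).
#' @return named list keyed "<angle>_offset<k>" over the five directions
#'   (four angles + AllDirection); empty combinations are NULL.
#' @export
glcmMatrices <- function(vol, offsets = textureOffsets()) {
  stopifnot(is(vol, "DiscreteVolume"))
  L <- nGrayLevels(vol)
  lev <- voxelData(vol)
  out <- list()
  for (o in offsets) {
    perAngle <- lapply(textureAngles(), function(a) glcmCounts(lev, L, a, o))
    names(perAngle) <- textureAngles()
    allDir <- Reduce(`+`, perAngle)
    for (a in textureAngles()) {
      tot <- sum(perAngle[[a]])
      out[[sprintf("%s_offset%d", a, o)]] <-
        if (tot > 0) matrix(perAngle[[a]] / tot, L, L) else NULL
    }
    tot <- sum(allDir)
    out[[sprintf("AllDirection_offset%d", o)]] <-
      if (tot > 0) matrix(allDir / tot, L, L) else NULL
  }
  out
}

# The 17 base statistics of one normalized co-occurrence matrix.
# Undefined values (zero marginal variance for Correlation) are NaN.
glcmFeatureSet <- function(P) {
  bases <- c(glcmCoreBases(), glcmExtendedBases(), clusterBases(),
             "Correlation", "HaralickCorrelation")
  if (is.null(P)) return(stats::setNames(rep(NaN, length(bases)), bases))
  L <- nrow(P)
  nz <- which(P > 0)
  p <- P[nz]
  i <- ((nz - 1L) %% L) + 1L
  j <- ((nz - 1L) %/% L) + 1L
  px <- rowSums(P)
  lv <- seq_len(L)
  mux <- sum(lv * px)
  vx <- sum((lv - mux)^2 * px)
  s <- i + j
  ps <- rowsum(p, s)
  ks <- as.numeric(rownames(ps))
  sumAvg <- sum(ks * ps)
  dd <- abs(i - j)
  pd <- rowsum(p, dd)
  kd <- as.numeric(rownames(pd))
  diffAvg <- sum(kd * pd)
  cc <- i + j - 2 * mux
  autocorr <- sum(i * j * p)
  stats::setNames(c(
    sum(p^2),                                   # GLCMEnergy
    shannonEntropy(p),                          # GLCMEntropy
    sum((i - j)^2 * p),                         # Inertia
    sum(p / (1 + (i - j)^2)),                   # InverseDifferenceMoment
    max(p),                                     # MaxProbability
    sumAvg,                                     # SumAverage
    shannonEntropy(ps),                         # SumEntropy
    sum((ks - sumAvg)^2 * ps),                  # SumVariance
    diffAvg,                                    # DifferenceAverage
    shannonEntropy(pd),                         # DifferenceEntropy
    sum((kd - diffAvg)^2 * pd),                 # DifferenceVariance
    sum((i - mux)^2 * p),                       # JointVariance
    sum(cc^3 * p),                              # ClusterShade
    sum(cc^4 * p),                              # ClusterProminence
    sum(cc^2 * p),                              # ClusterTendency
    if (vx > 0) (autocorr - mux^2) / vx else NaN,  # Correlation
    autocorr                                    # HaralickCorrelation
  ), c(glcmCoreBases(), "MaxProbability", "SumAverage", "SumEntropy",
       "SumVariance", "DifferenceAverage", "DifferenceEntropy",
       "DifferenceVariance", "JointVariance", "ClusterShade",
       "ClusterProminence", "ClusterTendency", "Correlation",
       "HaralickCorrelation"))
}

#' Co-occurrence-derived features (GLCM, cluster and correlation families)
#'
#' Evaluates the registry's GLCM, cluster and correlation features from a
#' set of co-occurrence matrices; empty matrices propagate NaN sentinels.
#'
#' @param matrices list from \code{\link{glcmMatrices}}.
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @return named numeric over the glcm, cluster and correlation entries of
#'   the catalog, in catalog order.
#' @export
computeGLCMFeatures <- function(matrices, catalog = defaultFeatureCatalog()) {
  sets <- lapply(matrices, glcmFeatureSet)
  entries <- catalogEntries(catalog)
  entries <- entries[entries$class %in% c("glcm", "cluster", "correlation"), ]
  vals <- vapply(seq_len(nrow(entries)), function(r) {
    key <- sprintf("%s_offset%d", entries$angle[r], entries$offset[r])
    fs <- sets[[key]]
    if (is.null(fs)) NaN else unname(fs[entries$base[r]])
  }, numeric(1))
  stats::setNames(vals, entries$name)
}

# --- run-length -----------------------------------------------------------

# Concatenate a slice's lines along `angle` into one vector with NA breaks.
sliceLines <- function(m, angle) {
  switch(angle,
    angle0   = as.vector(t(cbind(m, NA))),
    angle90  = as.vector(rbind(m, NA)),
    angle45  = unlist(lapply(split(m, col(m) - row(m)), c, NA), use.names = FALSE),
    angle135 = unlist(lapply(split(m, col(m) + row(m)), c, NA), use.names = FALSE),
    stop("unknown angle: ", angle))
}

#' Build a gray-level run-length matrix
#'
#' Counts of maximal runs of equal gray level along the given in-plane
#' direction, accumulated over axial slices; runs break at the mask
#' boundary. \code{angle = "AllDirection"} sums the four per-angle run
#' matrices.
#'
#' @param vol a \linkS4class{DiscreteVolume}.
#' @param angle one of the four angles or "AllDirection".
#' @return an L x maxRunLength matrix of run counts (unnormalized).
#' @export
buildRunLengthMatrix <- function(vol, angle) {
  stopifnot(is(vol, "DiscreteVolume"))
  if (angle == "AllDirection") {
    mats <- lapply(textureAngles(), function(a) buildRunLengthMatrix(vol, a))
    maxLen <- max(vapply(mats, ncol, integer(1)))
    out <- matrix(0, nrow(mats[[1]]), maxLen)
    for (mm in mats) out[, seq_len(ncol(mm))] <- out[, seq_len(ncol(mm))] + mm
    return(out)
  }
  L <- nGrayLevels(vol)
  lev <- voxelData(vol)
  d <- dim(lev)
  maxLen <- max(d[1], d[2])
  counts <- numeric(L * maxLen)
  for (k in seq_len(d[3])) {
    r <- rle(sliceLines(array(lev[, , k], d[1:2]), angle))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    idx <- (r$lengths[keep] - 1L) * L + r$values[keep]
    counts <- counts + tabulate(idx, nbins = L * maxLen)
  }
  matrix(counts, L, maxLen)
}

# The 12 run-length statistics of one run matrix; Np = in-mask voxel count.
rlmFeatureSet <- function(R, Np) {
  bases <- rlmBases()
  Nr <- sum(R)
  if (Nr == 0) return(stats::setNames(rep(NaN, length(bases)), bases))
  L <- nrow(R)
  lens <- seq_len(ncol(R))
  lvls <- seq_len(L)
  rg <- rowSums(R)                 # per gray level
  rl <- colSums(R)                 # per run length
  srE <- sum(rl / lens^2) / Nr
  lrE <- sum(rl * lens^2) / Nr
  muL <- sum(lens * rl) / Nr
  lowG <- sum(rg / lvls^2) / Nr
  highG <- sum(rg * lvls^2) / Nr
  invL2 <- outer(1 / lvls^2, 1 / lens^2)
  l2 <- outer(lvls^2, lens^2)
  stats::setNames(c(
    srE,
    lrE,
    sum(rg^2) / Nr,                          # GreyLevelNonuniformity
    sum(rl^2) / Nr,                          # RunLengthNonuniformity
    Nr / Np,                                 # RunPercentage
    lowG,
    highG,
    sum(R * invL2) / Nr,                     # ShortRunLowGreyLevelEmphasis
    sum(R * outer(lvls^2, 1 / lens^2)) / Nr, # ShortRunHighGreyLevelEmphasis
    sum(R * outer(1 / lvls^2, lens^2)) / Nr, # LongRunLowGreyLevelEmphasis
    sum(R * l2) / Nr,                        # LongRunHighGreyLevelEmphasis
    sum(t(R) * (lens - muL)^2) / Nr          # RunLengthVariance
  ), bases)
}

#' Run-length features over all directions and offset tags
#'
#' Run matrices are built per direction (plus AllDirection). Runs carry no
#' displacement, so the registry's offset tags of a direction are naming
#' replicas of the same per-direction value.
#'
#' @param vol a \linkS4class{DiscreteVolume}.
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @return named numeric over the catalog's rlm entries (180 by default).
#' @export
computeRLMFeatures <- function(vol, catalog = defaultFeatureCatalog()) {
  stopifnot(is(vol, "DiscreteVolume"))
  Np <- sum(!is.na(voxelData(vol)))
  dirs <- c(textureAngles(), "AllDirection")
  sets <- lapply(dirs, function(a) rlmFeatureSet(buildRunLengthMatrix(vol, a), Np))
  names(sets) <- dirs
  entries <- catalogEntries(catalog)
  entries <- entries[entries$class == "rlm", ]
  vals <- vapply(seq_len(nrow(entries)), function(r)
    unname(sets[[entries$angle[r]]][entries$base[r]]), numeric(1))
  stats::setNames(vals, entries$name)
}

# --- size zone ------------------------------------------------------------

#' Zones of a discretized VOI (26-connected, 3D)
#'
#' Maximal 26-connected components of equal gray level within the mask.
#'
#' @param vol a \linkS4class{DiscreteVolume}.
#' @return data.frame with columns level, size (one row per zone).
#' @export
zoneTable <- function(vol) {
  stopifnot(is(vol, "DiscreteVolume"))
  lev <- voxelData(vol)
  d <- dim(lev)
  inMask <- which(!is.na(lev))
  n <- length(inMask)
  if (n == 0L) return(data.frame(level = integer(), size = integer()))
  vid <- array(NA_integer_, d)
  vid[inMask] <- seq_len(n)
  shifts <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in 0:1) {
    if (dz == 0 && (dx < 0 || (dx == 0 && dy <= 0))) next  # half-space: 13 shifts
    shifts[[length(shifts) + 1L]] <- c(dx, dy, dz)
  }
  edges <- list()
  for (s in shifts) {
    bounds <- Map(function(n, sh) c(max(1L, 1L - sh), min(n, n - sh)), d, s)
    if (any(vapply(bounds, function(b) b[1] > b[2], logical(1)))) next
    xr <- bounds[[1]][1]:bounds[[1]][2]
    yr <- bounds[[2]][1]:bounds[[2]][2]
    zr <- bounds[[3]][1]:bounds[[3]][2]
    a <- lev[xr, yr, zr, drop = FALSE]
    b <- lev[xr + s[1], yr + s[2], zr + s[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (!any(ok)) next
    va <- vid[xr, yr, zr, drop = FALSE][ok]
    vb <- vid[xr + s[1], yr + s[2], zr + s[3], drop = FALSE][ok]
    edges[[length(edges) + 1L]] <- cbind(va, vb)
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_len(n)
  }
  size <- as.integer(table(comp))
  firstVoxel <- match(seq_along(size), comp)
  data.frame(level = lev[inMask][firstVoxel], size = size)
}

#' Compute the 11 size-zone (GLSZM) features
#'
#' @param vol a \linkS4class{DiscreteVolume}.
#' @return named numeric vector of length 11.
#' @export
computeGLSZMFeatures <- function(vol) {
  zones <- zoneTable(vol)
  bases <- glszmFeatureNames()
  Nz <- nrow(zones)
  if (Nz == 0L) return(stats::setNames(rep(NaN, length(bases)), bases))
  Np <- sum(zones$size)
  s <- zones$size
  g <- zones$level
  perLevel <- rowsum(rep(1, Nz), g)
  perSize <- rowsum(rep(1, Nz), s)
  stats::setNames(c(
    sum(1 / s^2) / Nz,                       # SmallAreaEmphasis
    sum(s^2) / Nz,                           # LargeAreaEmphasis
    sum(perLevel^2) / Nz,                    # GreyLevelZoneNonuniformity
    sum(perSize^2) / Nz,                     # SizeZoneNonuniformity
    Nz / Np,                                 # ZonePercentage
    sum(1 / g^2) / Nz,                       # LowGreyLevelZoneEmphasis
    sum(g^2) / Nz,                           # HighGreyLevelZoneEmphasis
    sum(1 / (g^2 * s^2)) / Nz,               # SmallAreaLowGreyLevelEmphasis
    sum(g^2 / s^2) / Nz,                     # SmallAreaHighGreyLevelEmphasis
    sum(s^2 / g^2) / Nz,                     # LargeAreaLowGreyLevelEmphasis
    sum(g^2 * s^2) / Nz                      # LargeAreaHighGreyLevelEmphasis
  ), bases)
}
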