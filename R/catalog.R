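# The versioned 396-feature registry.
#
# Class totals are fixed: 42 histogram + 9 form factor + 100 GLCM +
# 180 run-length + 11 size-zone + 36 cluster + 18 correlation = 396
# (345 texture features). The exact base x direction x offset composition
# is pinned here and asserted at load; it is never re-balanced.

CATALOG_VERSION <- "1.0"

catalogClassTotals <- c(histogram = 42L, form_factor = 9L, glcm = 100L,
                        rlm = 180L, glszm = 11L, cluster = 36L,
                        correlation = 18L)

histogramFeatureNames <- function() {
  stats <- c("Mean", "Median", "Minimum", "Maximum", "Range", "Variance",
             "StandardDeviation", "Skewness", "Kurtosis", "IntensityEnergy",
             "HistEnergy", "HistEntropy", "Uniformity", "RootMeanSquared",
             "MeanAbsoluteDeviation", "MedianAbsoluteDeviation",
             "RobustMeanAbsoluteDeviation", "InterquartileRange", "Sum",
             "Mode", "TrimmedMean")
  pct <- c("Quantile0.025", paste0("Percentile", seq(5, 95, by = 5)),
           "Quantile0.975")
  c(stats, pct)  # 21 + 21 = 42
}

shapeFeatureNames <- function() {
  c("VoxelCount", "Volume", "SurfaceArea", "SurfaceToVolumeRatio",
    "Compactness1", "Compactness2", "Sphericity", "SphericalDisproportion",
    "Maximum3DDiameter")
}

glszmFeatureNames <- function() {
  c("SmallAreaEmphasis", "LargeAreaEmphasis", "GreyLevelZoneNonuniformity",
    "SizeZoneNonuniformity", "ZonePercentage", "LowGreyLevelZoneEmphasis",
    "HighGreyLevelZoneEmphasis", "SmallAreaLowGreyLevelEmphasis",
    "SmallAreaHighGreyLevelEmphasis", "LargeAreaLowGreyLevelEmphasis",
    "LargeAreaHighGreyLevelEmphasis")
}

glcmCoreBases <- function() c("GLCMEnergy", "GLCMEntropy", "Inertia",
                              "InverseDifferenceMoment")

glcmExtendedBases <- function() {
  c("MaxProbability", "SumAverage", "SumEntropy", "SumVariance",
    "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
    "JointVariance")
}

rlmBases <- function() {
  c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
    "RunLengthNonuniformity", "RunPercentage", "LowGreyLevelRunEmphasis",
    "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
    "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
    "LongRunHighGreyLevelEmphasis", "RunLengthVariance")
}

clusterBases <- function() c("ClusterShade", "ClusterProminence",
                             "ClusterTendency")

textureAngles <- function() c("angle0", "angle45", "angle90", "angle135")
textureOffsets <- function() c(1L, 4L, 7L)

textureName <- function(base, angle, offset)
  sprintf("%s_%s_offset%d", base, angle, offset)

#' The default 396-feature catalog
#'
#' Builds the versioned feature registry. Composition (pinned, asserted):
#' \itemize{
#' \item histogram (42): 21 first-order statistics + 21 percentile features.
#' \item form_factor (9): volume/surface/compactness/diameter family.
#' \item glcm (100): 4 core bases (energy, entropy, inertia, inverse
#'   difference moment) at 5 directions (4 angles + AllDirection) x 3
#'   offsets (1, 4, 7) = 60, plus 8 extended bases at 5 directions,
#'   offset 1 = 40.
#' \item rlm (180): 12 run-length bases at 5 directions x 3 offset tags.
#'   Runs have no displacement, so the offset tag is a naming dimension
#'   only: the three tags of a direction carry the same value.
#' \item glszm (11): 3D 26-connected size-zone features (no direction).
#' \item cluster (36): cluster shade / prominence / tendency at the 4
#'   in-plane angles x 3 offsets.
#' \item correlation (18): Correlation at all 15 direction x offset
#'   combinations + HaralickCorrelation (raw second cross moment) at
#'   AllDirection x 3 offsets.
#' }
#'
#' @return a \linkS4class{FeatureCatalog} with exactly 396 entries.
#' @examples
#' cat <- defaultFeatureCatalog()
#' table(catalogEntries(cat)$class)
#' @export
defaultFeatureCatalog <- function() {
  dirs5 <- c(textureAngles(), "AllDirection")
  rows <- list()
  add <- function(name, class, base, angle = NA_character_, offset = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class, base = base, angle = angle,
      offset = as.integer(offset), stringsAsFactors = FALSE)
  }
  for (nm in histogramFeatureNames()) add(nm, "histogram", nm)
  for (nm in shapeFeatureNames()) add(nm, "form_factor", nm)
  for (b in glcmCoreBases())
    for (a in dirs5) for (o in textureOffsets())
      add(textureName(b, a, o), "glcm", b, a, o)
  for (b in glcmExtendedBases())
    for (a in dirs5)
      add(textureName(b, a, 1L), "glcm", b, a, 1L)
  for (b in rlmBases())
    for (a in dirs5) for (o in textureOffsets())
      add(textureName(b, a, o), "rlm", b, a, o)
  for (nm in glszmFeatureNames()) add(nm, "glszm", nm)
  for (b in clusterBases())
    for (a in textureAngles()) for (o in textureOffsets())
      add(textureName(b, a, o), "cluster", b, a, o)
  for (a in dirs5) for (o in textureOffsets())
    add(textureName("Correlation", a, o), "correlation", "Correlation", a, o)
  for (o in textureOffsets())
    add(textureName("HaralickCorrelation", "AllDirection", o), "correlation",
        "HaralickCorrelation", "AllDirection", o)
  entries <- do.call(rbind, rows)
  cat <- new("FeatureCatalog", entries = entries, version = CATALOG_VERSION)
  assertCatalogCounts(cat)
  cat
}

# Hard assertion of the printed class totals; called at registry load.
assertCatalogCounts <- function(catalog) {
  counts <- table(catalogEntries(catalog)$class)
  for (cl in names(catalogClassTotals)) {
    got <- if (cl %in% names(counts)) as.integer(counts[[cl]]) else 0L
    if (got != catalogClassTotals[[cl]])
      stop(sprintf("catalog class '%s': %d entries, expected %d", cl, got,
                   catalogClassTotals[[cl]]))
  }
  total <- nrow(catalogEntries(catalog))
  if (total != sum(catalogClassTotals))
    stop(sprintf("catalog has %d entries, expected %d", total,
                 sum(catalogClassTotals)))
  texture <- sum(catalogClassTotals[c("glcm", "rlm", "glszm", "cluster",
                                      "correlation")])
  stopifnot(texture == 345L)
  invisible(TRUE)
}

#' Write a catalog registry to JSON
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCatalogJSON <- function(catalog, path) {
  obj <- list(version = catalogVersion(catalog),
              class_totals = as.list(catalogClassTotals),
              entries = catalogEntries(catalog))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a catalog registry from JSON
#' @param path file written by \code{\link{writeCatalogJSON}}; by default the
#'   registry shipped with the package.
#' @return a \linkS4class{FeatureCatalog} (counts asserted at load).
#' @export
readCatalogJSON <- function(path = system.file("extdata",
                                               "feature-catalog-v1.json",
                                               package = "radirep")) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  entries$offset <- as.integer(entries$offset)
  cat <- new("FeatureCatalog", entries = entries,
             version = as.character(obj$version))
  assertCatalogCounts(cat)
  cat
}
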