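# Full catalog extraction: one value per registry entry.

#' Extract the full feature catalog from one session
#'
#' Histogram features are computed on the (optionally normalized)
#' continuous intensities, form-factor features on the mask geometry only,
#' and all texture families on the histogram-equalization discretized
#' volume, so texture values are exactly invariant under strictly monotone
#' intensity transforms of the raw image. Undefined values (degenerate
#' matrices, zero-variance correlation) are NaN sentinels, never dropped.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param mask a non-empty \linkS4class{VoxelMask} on the same grid.
#' @param catalog a \linkS4class{FeatureCatalog}
#'   (default \code{\link{defaultFeatureCatalog}}).
#' @param levels gray levels for discretization (default 256).
#' @param offsets co-occurrence offsets (default 1, 4, 7).
#' @param histBins bin count for histogram entropy/energy (default 256).
#' @return named numeric vector, one value per catalog entry in catalog
#'   order (396 for the default catalog).
#' @examples
#' ph <- generatePhantom(phantomSpec(), seed = 7)
#' fv <- extractAllFeatures(ph$image, ph$masks$tissue)
#' length(fv)
#' @export
extractAllFeatures <- function(image, mask, catalog = defaultFeatureCatalog(),
                               levels = 256L, offsets = textureOffsets(),
                               histBins = 256L) {
  stopifnot(is(image, "VolumeImage"), is(mask, "VoxelMask"),
            is(catalog, "FeatureCatalog"))
  dv <- discretizeVolume(image, mask, levels = levels)
  vals <- c(
    computeHistogramFeatures(image, mask, nBins = histBins),
    computeShapeFeatures(mask),
    computeGLCMFeatures(glcmMatrices(dv, offsets), catalog),
    computeRLMFeatures(dv, catalog),
    computeGLSZMFeatures(dv))
  nm <- names(catalog)
  missing <- setdiff(nm, names(vals))
  if (length(missing))
    stop("catalog entries not computed: ", paste(missing, collapse = ", "))
  out <- vals[nm]
  stopifnot(length(out) == nrow(catalogEntries(catalog)))
  out
}

#' Extract features for every session of a study
#'
#' Runs the standard per-session chain: isotropic resampling, optional
#' decile normalization against a reference landmark map, discretization
#' and full-catalog extraction.
#'
#' @param sessions session list as produced by \code{\link{generateStudy}}.
#' @param reference a \linkS4class{LandmarkMap} or NULL (raw arm).
#' @param catalog a \linkS4class{FeatureCatalog}.
#' @param targetSpacing isotropic spacing in mm.
#' @param maskName which mask to extract over (default "voi").
#' @param levels,offsets,histBins passed to \code{\link{extractAllFeatures}}.
#' @return data.frame: session metadata columns followed by one column per
#'   feature.
#' @export
extractStudyFeatures <- function(sessions, reference = NULL,
                                 catalog = defaultFeatureCatalog(),
                                 targetSpacing = 1, maskName = "voi",
                                 levels = 256L, offsets = textureOffsets(),
                                 histBins = 256L) {
  rows <- lapply(sessions, function(sess) {
    rs <- resampleIsotropic(sess$image, sess$masks[[maskName]], targetSpacing)
    img <- rs$image
    if (!is.null(reference))
      img <- applyDecileNormalization(img, rs$mask, reference)
    fv <- extractAllFeatures(img, rs$mask, catalog, levels = levels,
                             offsets = offsets, histBins = histBins)
    cbind(as.data.frame(sess$info, stringsAsFactors = FALSE),
          as.data.frame(t(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Metadata columns of a study feature table
#' @return character vector of the non-feature column names.
#' @export
sessionInfoColumns <- function() {
  c("session_id", "subject", "group", "layout", "arm", "scanner", "sweep",
    "level", "TR", "TE", "ST", "AM", "seed", "tissue")
}

#' Split a feature table into metadata and feature matrix
#' @param featureTable data.frame from \code{\link{extractStudyFeatures}}.
#' @return list with \code{info} (data.frame) and \code{values} (numeric
#'   matrix, sessions x features).
#' @export
splitFeatureTable <- function(featureTable) {
  meta <- intersect(sessionInfoColumns(), names(featureTable))
  featCols <- setdiff(names(featureTable), meta)
  list(info = featureTable[, meta, drop = FALSE],
       values = as.matrix(featureTable[, featCols, drop = FALSE]))
}
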