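# Constructors, generics, accessors and show methods.

#' Construct a VolumeImage
#' @param voxels numeric 3D array.
#' @param spacing mm per axis (length 3 or scalar).
#' @param meta named list of acquisition metadata.
#' @return a \linkS4class{VolumeImage}.
#' @export
VolumeImage <- function(voxels, spacing = c(1, 1, 1), meta = list()) {
  new("VolumeImage", voxels = voxels, spacing = rep_len(as.numeric(spacing), 3L),
      meta = meta)
}

#' Construct a VoxelMask
#' @param voxels logical (or coercible) 3D array.
#' @param spacing mm per axis.
#' @return a \linkS4class{VoxelMask}.
#' @export
VoxelMask <- function(voxels, spacing = c(1, 1, 1)) {
  v <- array(as.logical(voxels), dim(voxels))
  new("VoxelMask", voxels = v, spacing = rep_len(as.numeric(spacing), 3L))
}

#' @rdname voxelData
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Extract the voxel array of an image-like object
#'
#' @param x a VolumeImage, VoxelMask or DiscreteVolume.
#' @return the underlying 3D array (numeric, logical or integer-with-NA).
#' @export
setMethod("voxelData", "VolumeImage", function(x) x@voxels)

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelMask", function(x) x@voxels)

#' @rdname voxelData
#' @export
setMethod("voxelData", "DiscreteVolume", function(x) x@levels)

#' @rdname voxelSpacing
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Voxel spacing (mm per axis) of an image-like object
#' @param x a VolumeImage, VoxelMask or DiscreteVolume.
#' @return numeric length 3.
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "VoxelMask", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DiscreteVolume", function(x) x@spacing)

#' @rdname imageMeta
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))

#' Acquisition metadata of a volume
#' @param x a VolumeImage or DiscreteVolume.
#' @return named list.
#' @export
setMethod("imageMeta", "VolumeImage", function(x) x@meta)

#' @rdname imageMeta
#' @export
setMethod("imageMeta", "DiscreteVolume", function(x) x@meta)

#' @rdname nGrayLevels
#' @export
setGeneric("nGrayLevels", function(x) standardGeneric("nGrayLevels"))

#' Number of gray levels of a DiscreteVolume
#' @param x a DiscreteVolume.
#' @return integer L.
#' @export
setMethod("nGrayLevels", "DiscreteVolume", function(x) x@nLevels)

#' @rdname landmarkPercentiles
#' @export
setGeneric("landmarkPercentiles", function(x) standardGeneric("landmarkPercentiles"))

#' Percentile grid of a LandmarkMap
#' @param x a LandmarkMap.
#' @return numeric vector of percentiles (percent).
#' @export
setMethod("landmarkPercentiles", "LandmarkMap", function(x) x@percentiles)

#' @rdname landmarkIntensities
#' @export
setGeneric("landmarkIntensities", function(x) standardGeneric("landmarkIntensities"))

#' Landmark intensities of a LandmarkMap
#' @param x a LandmarkMap.
#' @return numeric vector, non-decreasing.
#' @export
setMethod("landmarkIntensities", "LandmarkMap", function(x) x@intensities)

#' @rdname catalogEntries
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))

#' Registry table of a FeatureCatalog
#' @param x a FeatureCatalog.
#' @return data.frame with columns name, class, base, angle, offset.
#' @export
setMethod("catalogEntries", "FeatureCatalog", function(x) x@entries)

#' @rdname catalogVersion
#' @export
setGeneric("catalogVersion", function(x) standardGeneric("catalogVersion"))

#' Version string of a FeatureCatalog
#' @param x a FeatureCatalog.
#' @return character scalar.
#' @export
setMethod("catalogVersion", "FeatureCatalog", function(x) x@version)

#' Feature names of a catalog
#' @param x a FeatureCatalog.
#' @return character vector of the ordered feature names.
#' @export
setMethod("names", "FeatureCatalog", function(x) x@entries$name)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeImage %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@voxels), max(object@voxels)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelMask %d x %d x %d, %d in-mask voxels\n",
              d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "DiscreteVolume", function(object) {
  d <- dim(object@levels)
  cat(sprintf("DiscreteVolume %d x %d x %d, L = %d, %d in-mask voxels\n",
              d[1], d[2], d[3], object@nLevels, sum(!is.na(object@levels))))
})

setMethod("show", "LandmarkMap", function(object) {
  cat(sprintf("LandmarkMap (reference '%s')\n", object@referenceId))
  print(stats::setNames(signif(object@intensities, 5),
                        paste0("p", object@percentiles)))
})

setMethod("show", "FeatureCatalog", function(object) {
  cat(sprintf("FeatureCatalog v%s: %d features\n", object@version,
              nrow(object@entries)))
  print(table(object@entries$class))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s', grid %s, spacing %s mm\n", object@layout,
              paste(object@gridShape, collapse = "x"),
              paste(signif(object@voxelSpacing, 3), collapse = "x")))
})

setMethod("show", "ScannerEffect", function(object) {
  cat(sprintf(paste0("ScannerEffect gain=%.3g offset=%.3g gamma=%.3g ",
                     "rician=%.3g downsample=%.3g sliceMerge=%d blur=%.3g mm\n"),
              object@gain, object@offset, object@gamma, object@ricianSigma,
              object@inplaneDownsample, object@sliceMerge, object@blurFWHM))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d subjects, %d scanners, %d sweeps, seed %d\n",
              nrow(object@subjects), length(object@scanners),
              length(object@sweeps), object@masterSeed))
})
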