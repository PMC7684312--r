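#' @import methods
NULL

#' VolumeImage: a 3D grayscale volume with voxel spacing and scan metadata
#'
#' The basic image container of the package: a numeric 3D array of
#' intensities (arbitrary units, as on a T2-weighted series), the physical
#' voxel spacing in mm per axis, and a free-form metadata list carrying scan
#' provenance (subject, group, scanner, TR, TE, slice thickness, acquisition
#' matrix, session id).
#'
#' @slot voxels numeric 3D array of intensities.
#' @slot spacing numeric length-3, mm per axis, all positive.
#' @slot meta named list of acquisition metadata.
#' @export
setClass("VolumeImage",
  representation(voxels = "array", spacing = "numeric", meta = "list"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1), meta = list()))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
  if (any(!is.finite(object@voxels))) return("intensities must be finite")
  TRUE
})

#' VoxelMask: a binary volume of interest aligned to a VolumeImage
#'
#' @slot voxels logical 3D array; TRUE marks in-mask voxels.
#' @slot spacing numeric length-3, mm per axis.
#' @export
setClass("VoxelMask",
  representation(voxels = "array", spacing = "numeric"),
  prototype(voxels = array(TRUE, c(1, 1, 1)), spacing = c(1, 1, 1)))

setValidity("VoxelMask", function(object) {
  if (length(dim(object@voxels)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@voxels)) return("mask voxels must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers")
  TRUE
})

#' DiscreteVolume: gray-level discretized volume
#'
#' Integer gray levels in [1, L] inside the mask; voxels outside the mask
#' carry the sentinel NA and never enter any texture matrix or statistic.
#'
#' @slot levels integer 3D array with NA outside the mask.
#' @slot nLevels integer, the number of gray levels L.
#' @slot spacing numeric length-3, mm.
#' @slot meta provenance list inherited from the source image.
#' @export
setClass("DiscreteVolume",
  representation(levels = "array", nLevels = "integer", spacing = "numeric",
                 meta = "list"),
  prototype(levels = array(NA_integer_, c(1, 1, 1)), nLevels = 256L,
            spacing = c(1, 1, 1), meta = list()))

setValidity("DiscreteVolume", function(object) {
  v <- object@levels[!is.na(object@levels)]
  if (length(v) && (min(v) < 1L || max(v) > object@nLevels))
    return("in-mask levels must lie in [1, nLevels]")
  if (object@nLevels < 1L) return("nLevels must be >= 1")
  TRUE
})

#' LandmarkMap: percentile landmarks of a reference volume
#'
#' The reference side of decile piecewise-linear intensity normalization:
#' the percentile grid (default 5, 10, 20, ..., 90, 95 percent) and the
#' corresponding in-mask intensities of the reference image.
#'
#' @slot percentiles numeric, strictly increasing, in (0, 100).
#' @slot intensities numeric, same length, non-decreasing.
#' @slot referenceId character scalar naming the reference session.
#' @export
setClass("LandmarkMap",
  representation(percentiles = "numeric", intensities = "numeric",
                 referenceId = "character"),
  prototype(percentiles = numeric(), intensities = numeric(),
            referenceId = NA_character_))

setValidity("LandmarkMap", function(object) {
  p <- object@percentiles
  if (length(p) != length(object@intensities))
    return("percentiles and intensities must have equal length")
  if (length(p) && (any(p <= 0) || any(p >= 100) || any(diff(p) <= 0)))
    return("percentiles must be strictly increasing in (0, 100)")
  if (length(p) && any(diff(object@intensities) < 0))
    return("landmark intensities must be non-decreasing")
  TRUE
})

#' PhantomSpec: geometry and texture of a synthetic phantom
#'
#' Describes either a single-tissue textured phantom (a kiwi-fruit analog:
#' one roughly cylindrical tissue) or a two-layer phantom (a cervix analog:
#' an inner core and a surrounding outer ring, delineated separately).
#' Per-tissue texture is a Gaussian random field with a stated correlation
#' length plus independent voxel noise.
#'
#' @slot gridShape integer length-3 voxel grid, all >= 8.
#' @slot voxelSpacing numeric length-3 mm, positive.
#' @slot layout "kiwi" (single tissue) or "cervix" (inner + outer layer).
#' @slot tissueMeans numeric mean intensity per tissue (1 or 2 values).
#' @slot textureCorrLength numeric mm per tissue, >= 0.
#' @slot textureAmplitude numeric per tissue, >= 0.
#' @slot noiseSigma numeric scalar, independent voxel noise SD, >= 0.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacing = "numeric",
                 layout = "character", tissueMeans = "numeric",
                 textureCorrLength = "numeric", textureAmplitude = "numeric",
                 noiseSigma = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("gridShape must be 3 integers, all >= 8")
  if (any(object@voxelSpacing <= 0)) return("voxelSpacing must be positive")
  if (!object@layout %in% c("kiwi", "cervix"))
    return("layout must be 'kiwi' or 'cervix'")
  nt <- if (object@layout == "kiwi") 1L else 2L
  if (length(object@tissueMeans) != nt)
    return(sprintf("layout '%s' needs %d tissue mean(s)", object@layout, nt))
  if (length(object@textureCorrLength) != nt || any(object@textureCorrLength < 0))
    return("textureCorrLength must be >= 0, one per tissue")
  if (length(object@textureAmplitude) != nt || any(object@textureAmplitude < 0))
    return("textureAmplitude must be >= 0, one per tissue")
  if (length(object@noiseSigma) != 1L || object@noiseSigma < 0)
    return("noiseSigma must be a single value >= 0")
  TRUE
})

#' ScannerEffect: a monotone scanner/acquisition transform
#'
#' Emulates what a different scanner or acquisition setting does to the same
#' object: a strictly increasing intensity map x -> gain * x^gamma + offset,
#' optional contrast blur (FWHM in mm), in-plane downsampling (acquisition
#' matrix), adjacent-slice averaging (slice thickness / partial volume), and
#' Rician magnitude noise.
#'
#' @slot gain multiplicative factor, > 0.
#' @slot offset additive term.
#' @slot gamma power nonlinearity, > 0.
#' @slot ricianSigma Rician noise scale, >= 0.
#' @slot inplaneDownsample factor >= 1 applied to in-plane spacing.
#' @slot sliceMerge integer >= 1, adjacent slices averaged per output slice.
#' @slot blurFWHM Gaussian blur FWHM in mm, >= 0.
#' @export
setClass("ScannerEffect",
  representation(gain = "numeric", offset = "numeric", gamma = "numeric",
                 ricianSigma = "numeric", inplaneDownsample = "numeric",
                 sliceMerge = "integer", blurFWHM = "numeric"),
  prototype(gain = 1, offset = 0, gamma = 1, ricianSigma = 0,
            inplaneDownsample = 1, sliceMerge = 1L, blurFWHM = 0))

setValidity("ScannerEffect", function(object) {
  if (object@gain <= 0) return("gain must be > 0 (monotone map)")
  if (object@gamma <= 0) return("gamma must be > 0 (monotone map)")
  if (object@ricianSigma < 0) return("ricianSigma must be >= 0")
  if (object@inplaneDownsample < 1) return("inplaneDownsample must be >= 1")
  if (object@sliceMerge < 1L) return("sliceMerge must be >= 1")
  if (object@blurFWHM < 0) return("blurFWHM must be >= 0")
  TRUE
})

#' StudyDesign: a multi-scanner / parameter-sweep acquisition plan
#'
#' One inter-scanner arm (every subject once on every scanner at a shared
#' nominal setting) and one intra-scanner arm (every subject once per level
#' of each acquisition-parameter sweep, everything else held fixed).
#'
#' @slot subjects data.frame with columns subject, group, layout.
#' @slot scanners named list of ScannerEffect, one per scanner.
#' @slot sweeps named list (TR/TE/ST/AM-like); each element is a named list
#'   of ScannerEffect deltas applied on top of the first scanner.
#' @slot sweepLabels named list of numeric/character level labels parallel
#'   to sweeps (e.g. TR ms values).
#' @slot phantomSpecs named list with one PhantomSpec per layout.
#' @slot masterSeed integer.
#' @export
setClass("StudyDesign",
  representation(subjects = "data.frame", scanners = "list", sweeps = "list",
                 sweepLabels = "list", phantomSpecs = "list",
                 masterSeed = "integer"))

setValidity("StudyDesign", function(object) {
  if (!all(c("subject", "group", "layout") %in% names(object@subjects)))
    return("subjects needs columns subject, group, layout")
  if (nrow(object@subjects) < 1L) return("at least one subject required")
  if (length(object@scanners) < 1L) return("at least one scanner required")
  if (!all(vapply(object@scanners, is, logical(1), "ScannerEffect")))
    return("scanners must all be ScannerEffect")
  if (length(object@sweeps) && any(vapply(object@sweeps, length, integer(1)) == 0L))
    return("empty parameter sweeps are not allowed")
  if (!all(object@subjects$layout %in% names(object@phantomSpecs)))
    return("every subject layout needs a PhantomSpec")
  TRUE
})

#' FeatureCatalog: the versioned registry of feature definitions
#'
#' An ordered registry of named feature definitions. The default catalog
#' contains exactly 396 entries: 42 histogram, 9 form factor, 100 GLCM,
#' 180 run-length, 11 size-zone, 36 cluster and 18 correlation features.
#'
#' @slot entries data.frame with columns name, class, base, angle, offset.
#' @slot version character version id of the registry.
#' @export
setClass("FeatureCatalog",
  representation(entries = "data.frame", version = "character"))

setValidity("FeatureCatalog", function(object) {
  need <- c("name", "class", "base", "angle", "offset")
  if (!all(need %in% names(object@entries)))
    return("entries needs columns name, class, base, angle, offset")
  if (anyDuplicated(object@entries$name)) return("feature names must be unique")
  TRUE
})
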