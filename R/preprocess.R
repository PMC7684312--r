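# Geometric and gray-level standardization before feature extraction.

#' Resample an image and its mask to isotropic voxels
#'
#' Cubic interpolation for intensities, nearest-neighbour for the mask
#' (re-binarized). The output grid along each axis has
#' \code{floor(extent / target) + 1} voxels, where extent is the
#' voxel-centre extent \code{(n - 1) * spacing}. Input already at the target
#' spacing passes through unchanged.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param mask a \linkS4class{VoxelMask} on the same grid.
#' @param targetSpacing target spacing in mm (scalar or length 3), default 1.
#' @return list with elements \code{image} and \code{mask}.
#' @export
resampleIsotropic <- function(image, mask, targetSpacing = 1) {
  stopifnot(is(image, "VolumeImage"), is(mask, "VoxelMask"))
  target <- rep_len(as.numeric(targetSpacing), 3L)
  if (any(!is.finite(target)) || any(target <= 0))
    stop("targetSpacing must be positive")
  sp <- voxelSpacing(image)
  if (!identical(dim(voxelData(image)), dim(voxelData(mask))))
    stop("image and mask grids differ")
  if (isTRUE(all.equal(sp, target)))
    return(list(image = image, mask = mask))
  vol <- resampleArray(voxelData(image), sp, target, method = "cubic")
  m <- resampleArray(voxelData(mask) * 1, sp, target, method = "nearest")
  list(image = VolumeImage(vol, target, imageMeta(image)),
       mask = VoxelMask(m >= 0.5, target))
}

#' Bias-field correction hook (identity)
#'
#' Placeholder for an external bias-field correction step. The synthetic
#' phantoms are bias-free, so the default implementation returns its input
#' unchanged; supply \code{fun} to plug in a real corrector.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param fun optional function \code{VolumeImage -> VolumeImage}.
#' @return a \linkS4class{VolumeImage}.
#' @export
biasFieldHook <- function(image, fun = NULL) {
  if (is.null(fun)) image else fun(image)
}

#' Co-registration hook (identity)
#'
#' Placeholder for motion co-registration across sessions; synthetic
#' sessions are generated pre-aligned, so the default is the identity.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param reference ignored by the identity implementation.
#' @param fun optional function \code{(image, reference) -> VolumeImage}.
#' @return a \linkS4class{VolumeImage}.
#' @export
registrationHook <- function(image, reference = NULL, fun = NULL) {
  if (is.null(fun)) image else fun(image, reference)
}

#' Discretize in-mask intensities to L gray levels by histogram equalization
#'
#' In-mask intensities are mapped through their empirical CDF (midpoint
#' convention for ties) and quantized as \code{ceiling(L * ecdf(x))},
#' clamped to [1, L]. The mapping depends on intensity ranks only, so any
#' strictly monotone transform of the input yields the identical
#' DiscreteVolume — the formal reason texture features can be robust to
#' monotone scanner differences. A constant in-mask image maps every voxel
#' to level 1 (degenerate CDF; documented, not an error). Out-of-mask
#' voxels carry NA and never enter any texture matrix.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param mask a non-empty \linkS4class{VoxelMask} on the same grid.
#' @param levels number of gray levels L (default 256).
#' @return a \linkS4class{DiscreteVolume}.
#' @export
discretizeVolume <- function(image, mask, levels = 256L) {
  stopifnot(is(image, "VolumeImage"), is(mask, "VoxelMask"))
  L <- as.integer(levels)
  if (L < 1L) stop("levels must be >= 1")
  m <- voxelData(mask)
  if (!any(m)) stop("mask is empty")
  x <- voxelData(image)[m]
  out <- array(NA_integer_, dim(voxelData(image)))
  if (length(unique(x)) == 1L) {
    out[m] <- 1L
  } else {
    n <- length(x)
    r <- rank(x, ties.method = "average")   # midpoint ECDF: (#less + (#eq+1)/2)/n
    lev <- as.integer(ceiling(L * (r - 0.5) / n))
    out[m] <- pmin(L, pmax(1L, lev))
  }
  new("DiscreteVolume", levels = out, nLevels = L,
      spacing = voxelSpacing(image), meta = imageMeta(image))
}
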