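# Geometric ("form factor") features of the VOI mask.

# Exposed-face surface area in mm^2: every voxel face adjacent to an
# out-of-mask voxel (or the volume border) contributes the face area.
exposedFaceArea <- function(m, spacing) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  faceAreas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  shifts <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L),
                 c(0L, 0L, 1L), c(0L, 0L, -1L))
  core <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  area <- 0
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    nb <- pad[core[[1]] + s[1], core[[2]] + s[2], core[[3]] + s[3]]
    area <- area + faceAreas[ceiling(k / 2)] * sum(m & !nb)
  }
  area
}

# Voxels with at least one exposed face (used to bound the diameter search).
boundaryVoxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  core <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  interior <- array(TRUE, d)
  for (s in list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L),
                 c(0L, 0L, 1L), c(0L, 0L, -1L))) {
    interior <- interior & pad[core[[1]] + s[1], core[[2]] + s[2], core[[3]] + s[3]]
  }
  m & !interior
}

#' Compute the 9 form-factor (shape) features
#'
#' Volume (voxel count times voxel volume), exposed-face surface area,
#' surface-to-volume ratio, Compactness1 \eqn{V / (\sqrt{\pi} A^{3/2})},
#' Compactness2 \eqn{36 \pi V^2 / A^3}, Sphericity
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}, Spherical Disproportion
#' \eqn{A / (4 \pi R^2)} with \eqn{R} the equivalent-sphere radius (so
#' Sphericity times Spherical Disproportion is identically 1), the maximum
#' 3D diameter (largest pairwise distance between in-mask voxel centres, in
#' mm) and the voxel count. Shape depends on the mask only, never on
#' intensities.
#'
#' @param mask a non-empty \linkS4class{VoxelMask}.
#' @param spacing optional spacing override (mm).
#' @return named numeric vector of length 9.
#' @export
computeShapeFeatures <- function(mask, spacing = NULL) {
  stopifnot(is(mask, "VoxelMask"))
  m <- voxelData(mask)
  if (!any(m)) stop("mask is empty")
  sp <- if (is.null(spacing)) voxelSpacing(mask) else rep_len(spacing, 3L)
  n <- sum(m)
  V <- n * prod(sp)
  A <- exposedFaceArea(m, sp)
  R <- (3 * V / (4 * pi))^(1 / 3)
  bnd <- boundaryVoxels(m)
  idx <- which(bnd, arr.ind = TRUE)
  coords <- sweep(idx - 1, 2, sp, `*`)
  maxDiam <- 0
  nb <- nrow(coords)
  if (nb > 1L) {
    # chunked pairwise search over boundary voxels
    chunk <- 512L
    for (start in seq(1L, nb, by = chunk)) {
      rows <- start:min(start + chunk - 1L, nb)
      d2 <- outer(rowSums(coords[rows, , drop = FALSE]^2), rowSums(coords^2), `+`) -
        2 * coords[rows, , drop = FALSE] %*% t(coords)
      maxDiam <- max(maxDiam, sqrt(max(pmax(d2, 0))))
    }
  }
  c(VoxelCount = n,
    Volume = V,
    SurfaceArea = A,
    SurfaceToVolumeRatio = A / V,
    Compactness1 = V / (sqrt(pi) * A^1.5),
    Compactness2 = 36 * pi * V^2 / A^3,
    Sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    SphericalDisproportion = A / (4 * pi * R^2),
    Maximum3DDiameter = maxDiam)
}
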