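# Internal numeric helpers shared across modules.

#' Derive a reproducible session seed from a master seed and string tokens
#'
#' Folds the master seed and an arbitrary list of character/numeric tokens
#' into a 31-bit integer with a multiplicative string hash, so that every
#' (subject, condition) cell of a study design is independently reproducible
#' from the master seed alone.
#'
#' @param master integer master seed.
#' @param ... tokens (coerced to character) identifying the cell.
#' @return a single integer in [0, 2^31 - 2].
#' @export
deriveSeed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  mod <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(master) %% mod
  tokens <- vapply(list(...), function(t) paste(as.character(t), collapse = ","),
                   character(1))
  for (tok in tokens) {
    for (code in utf8ToInt(paste0("|", tok))) {
      h <- (h * 31 + code) %% mod
    }
  }
  as.integer(h)
}

# 1D Gaussian kernel, truncated at 3 sigma, normalized.
gaussKernel1D <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve each line of `arr` along `axis` with kernel `k`, replicating edges.
convolveAxis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  n <- nrow(m)
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
  }
  dim(out) <- dm
  aperm(out, order(perm))
}

# Separable Gaussian smoothing of a 3D array; sigma given per-axis in voxels.
gaussianSmooth3D <- function(arr, sigmaVox) {
  sigmaVox <- rep_len(sigmaVox, 3L)
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0) arr <- convolveAxis(arr, gaussKernel1D(sigmaVox[ax]), ax)
  }
  arr
}

# Output grid size for resampling: voxel-center extent rule
# n_out = floor((n_in - 1) * spacing_in / spacing_out) + 1.
resampledLength <- function(n, spacingIn, spacingOut) {
  as.integer(floor((n - 1L) * spacingIn / spacingOut)) + 1L
}

# Interpolate every line of a 3D array along one axis onto new coordinates.
# method "cubic" uses a natural cubic spline per line, "nearest" snaps to the
# closest source sample (used for masks).
resampleAxis <- function(arr, axis, oldCoords, newCoords, method = "cubic") {
  d <- dim(arr)
  if (length(oldCoords) != d[axis]) stop("coordinate/axis length mismatch")
  if (isTRUE(all.equal(oldCoords, newCoords))) return(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  if (method == "nearest") {
    idx <- vapply(newCoords, function(x) which.min(abs(oldCoords - x)), integer(1))
    out <- m[idx, , drop = FALSE]
  } else if (dm[1] < 4L) {
    # too few samples for a cubic fit: linear interpolation with edge clamp
    out <- apply(m, 2, function(line)
      stats::approx(oldCoords, line, xout = newCoords, rule = 2)$y)
    out <- matrix(out, nrow = length(newCoords))
  } else {
    out <- apply(m, 2, function(line)
      stats::splinefun(oldCoords, line, method = "natural")(newCoords))
    out <- matrix(out, nrow = length(newCoords))
  }
  dim(out) <- c(length(newCoords), dm[-1])
  aperm(out, order(perm))
}

# Resample a 3D array from oldSpacing to newSpacing (mm per axis).
resampleArray <- function(arr, oldSpacing, newSpacing, method = "cubic") {
  stopifnot(length(dim(arr)) == 3L, all(oldSpacing > 0), all(newSpacing > 0))
  newSpacing <- rep_len(newSpacing, 3L)
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    nOut <- resampledLength(n, oldSpacing[ax], newSpacing[ax])
    oldCoords <- (seq_len(n) - 1) * oldSpacing[ax]
    newCoords <- (seq_len(nOut) - 1) * newSpacing[ax]
    arr <- resampleAxis(arr, ax, oldCoords, newCoords, method)
  }
  arr
}

# 0*log2(0) := 0 convention used by every entropy in the package.
xlog2x <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

shannonEntropy <- function(p) -sum(xlog2x(p))
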