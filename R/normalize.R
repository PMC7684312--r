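# Decile piecewise-linear intensity normalization.
#
# Non-quantitative MR intensities are harmonized by matching percentile
# landmarks of each source image to those of a chosen reference: in-mask
# intensities are mapped through a monotone piecewise-cubic function fitted
# to the (source landmark -> reference landmark) knots, with linear
# continuation of the terminal segments beyond the outermost landmarks
# (the extreme tails are deliberately not trusted: they are noise-dominated).

#' Default landmark percentile grid
#'
#' The 11-entry percentile grid 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95
#' (percent) used for decile normalization.
#'
#' @return numeric vector of percentiles.
#' @export
defaultLandmarkPercentiles <- function() c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 95)

#' Compute the percentile landmarks of an image over a mask
#'
#' Empirical percentiles (linear-interpolation quantiles, R type 7) of the
#' in-mask intensities. Any exclusion regions (e.g. a bladder-like
#' high-signal structure) must already have been removed from the mask.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param mask a non-empty \linkS4class{VoxelMask}.
#' @param percentiles percentile grid in percent, strictly increasing in
#'   (0, 100); default \code{\link{defaultLandmarkPercentiles}}.
#' @param referenceId label recorded in the map.
#' @return a \linkS4class{LandmarkMap}.
#' @export
computeLandmarks <- function(image, mask,
                             percentiles = defaultLandmarkPercentiles(),
                             referenceId = "reference") {
  stopifnot(is(image, "VolumeImage"), is(mask, "VoxelMask"))
  m <- voxelData(mask)
  if (!any(m)) stop("mask is empty")
  x <- voxelData(image)[m]
  q <- unname(stats::quantile(x, probs = percentiles / 100, type = 7))
  new("LandmarkMap", percentiles = as.numeric(percentiles),
      intensities = q, referenceId = as.character(referenceId))
}

# Fritsch-Carlson slopes for a monotone cubic Hermite interpolant through
# non-decreasing data: secant-based tangents, zeroed at flat/reversing
# segments and limited to the alpha^2 + beta^2 <= 9 disc, which guarantees
# the piecewise cubic is monotone (the stats::splinefun "monoH.FC" filter
# can still overshoot on some knot sets, so the limiter is applied here).
fritschCarlsonSlopes <- function(xs, ys) {
  n <- length(xs)
  h <- diff(xs)
  delta <- diff(ys) / h
  m <- numeric(n)
  m[1] <- delta[1]
  m[n] <- delta[n - 1]
  if (n > 2)
    m[2:(n - 1)] <- (delta[1:(n - 2)] + delta[2:(n - 1)]) / 2
  for (i in seq_len(n - 1)) {
    if (delta[i] == 0) {
      m[i] <- 0
      m[i + 1] <- 0
    } else {
      a <- m[i] / delta[i]
      b <- m[i + 1] / delta[i]
      r <- a^2 + b^2
      if (r > 9) {
        tau <- 3 / sqrt(r)
        m[i] <- tau * a * delta[i]
        m[i + 1] <- tau * b * delta[i]
      }
    }
  }
  m
}

# Evaluate the cubic Hermite interpolant with knots (xs, ys), slopes m.
hermiteEval <- function(x, xs, ys, m) {
  i <- findInterval(x, xs, all.inside = TRUE)
  h <- xs[i + 1] - xs[i]
  t <- (x - xs[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * ys[i] + h10 * h * m[i] + h01 * ys[i + 1] + h11 * h * m[i + 1]
}

# Build the monotone landmark-matching map as a vectorized function.
# Knots: (source landmarks -> reference landmarks); inside the knot range a
# shape-preserving monotone piecewise cubic (Fritsch-Carlson), outside a
# linear continuation of the terminal segments.
landmarkMapFunction <- function(srcLandmarks, refLandmarks) {
  keep <- !duplicated(srcLandmarks)
  xs <- srcLandmarks[keep]
  # tied source knots: average the reference values they map to
  ys <- vapply(xs, function(x) mean(refLandmarks[srcLandmarks == x]), numeric(1))
  if (length(xs) < 2L) return(NULL)  # degenerate source
  m <- fritschCarlsonSlopes(xs, ys)
  n <- length(xs)
  sLow <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  sHigh <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
  function(x) {
    out <- hermiteEval(x, xs, ys, m)
    lo <- x < xs[1]
    hi <- x > xs[n]
    out[lo] <- ys[1] + sLow * (x[lo] - xs[1])
    out[hi] <- ys[n] + sHigh * (x[hi] - xs[n])
    out
  }
}

#' Normalize a source image to a reference landmark map
#'
#' The source image's own landmarks (same percentile grid as the reference)
#' are matched to the reference landmarks by a monotone piecewise-cubic map
#' (Fritsch--Carlson shape-preserving interpolant: an unconstrained cubic
#' through arbitrary knots can overshoot and invert tissue contrast).
#' Intensities beyond the outermost source landmarks follow the linear
#' extension of the terminal segments. A degenerate source whose landmarks
#' are all equal maps to the reference median, with a warning.
#'
#' @param source a \linkS4class{VolumeImage}.
#' @param sourceMask a non-empty \linkS4class{VoxelMask} (exclusions already
#'   removed).
#' @param reference a \linkS4class{LandmarkMap}.
#' @param applyTo "all" (default) transforms the whole volume with the
#'   fitted map; "mask" transforms in-mask voxels only.
#' @return a \linkS4class{VolumeImage} with normalized intensities.
#' @export
applyDecileNormalization <- function(source, sourceMask, reference,
                                     applyTo = c("all", "mask")) {
  stopifnot(is(source, "VolumeImage"), is(sourceMask, "VoxelMask"),
            is(reference, "LandmarkMap"))
  validObject(reference)
  applyTo <- match.arg(applyTo)
  src <- computeLandmarks(source, sourceMask, landmarkPercentiles(reference))
  mapFun <- landmarkMapFunction(landmarkIntensities(src),
                                landmarkIntensities(reference))
  vol <- voxelData(source)
  if (is.null(mapFun)) {
    warning("degenerate source: all landmarks equal; mapping to reference median")
    med <- stats::median(landmarkIntensities(reference))
    if (applyTo == "all") vol[] <- med else vol[voxelData(sourceMask)] <- med
    return(VolumeImage(vol, voxelSpacing(source), imageMeta(source)))
  }
  if (applyTo == "all") {
    vol[] <- mapFun(as.numeric(vol))
  } else {
    m <- voxelData(sourceMask)
    vol[m] <- mapFun(vol[m])
  }
  VolumeImage(vol, voxelSpacing(source), imageMeta(source))
}

#' Serialize a LandmarkMap to JSON
#' @param map a \linkS4class{LandmarkMap}.
#' @param path file path; when NULL the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
writeLandmarkJSON <- function(map, path = NULL) {
  obj <- list(reference_id = map@referenceId, percentiles = map@percentiles,
              intensities = map@intensities)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a LandmarkMap from JSON
#' @param path file written by \code{\link{writeLandmarkJSON}}.
#' @return a \linkS4class{LandmarkMap}.
#' @export
readLandmarkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("LandmarkMap", percentiles = as.numeric(obj$percentiles),
      intensities = as.numeric(obj$intensities),
      referenceId = as.character(obj$reference_id))
}
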