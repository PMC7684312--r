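# First-order (histogram) features of in-mask intensities.

#' Compute the 42 histogram features
#'
#' First-order statistics of the in-mask intensities: location, dispersion
#' and shape moments, binned histogram energy/entropy (log base 2), the
#' percentile family, and robust dispersion statistics. Moments use the
#' population (N denominator) convention. \code{HistEnergy}/\code{HistEntropy}
#' and \code{Mode} are computed on an equal-width histogram with
#' \code{nBins} bins over the in-mask range; \code{Uniformity} is the sum of
#' squared probabilities of the distinct observed values. A constant region
#' is well-defined: variance 0, entropy 0, uniformity 1, skewness and
#' kurtosis reported as 0 (no dispersion, no asymmetry).
#'
#' @param image a \linkS4class{VolumeImage} (or a numeric vector of in-mask
#'   intensities).
#' @param mask a non-empty \linkS4class{VoxelMask}; ignored when
#'   \code{image} is already a vector.
#' @param nBins histogram bin count for entropy/energy/mode (default 256).
#' @return named numeric vector of length 42.
#' @export
computeHistogramFeatures <- function(image, mask = NULL, nBins = 256L) {
  x <- if (is.numeric(image)) image else {
    stopifnot(is(image, "VolumeImage"), is(mask, "VoxelMask"))
    m <- voxelData(mask)
    if (!any(m)) stop("mask is empty")
    voxelData(image)[m]
  }
  if (!length(x)) stop("no in-mask intensities")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  rng <- range(x)
  # binned histogram over the in-mask range (single bin when constant)
  if (rng[1] == rng[2]) {
    p <- 1
    mode <- rng[1]
  } else {
    breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
    cnt <- graphics::hist(x, breaks = breaks, plot = FALSE, right = TRUE,
                          include.lowest = TRUE)$counts
    p <- cnt / n
    mode <- (breaks[which.max(cnt)] + breaks[which.max(cnt) + 1L]) / 2
  }
  valueProbs <- as.numeric(table(x)) / n
  q <- stats::quantile(x, probs = c(0.025, seq(0.05, 0.95, by = 0.05), 0.975,
                                    0.10, 0.25, 0.75, 0.90),
                       type = 7, names = FALSE)
  pcts <- q[1:21]
  p10 <- q[22]; p25 <- q[23]; p75 <- q[24]; p90 <- q[25]
  inRobust <- x >= p10 & x <= p90
  robustMAD <- if (any(inRobust)) mean(abs(x[inRobust] - mean(x[inRobust]))) else 0
  out <- c(
    Mean = mu,
    Median = stats::median(x),
    Minimum = rng[1],
    Maximum = rng[2],
    Range = rng[2] - rng[1],
    Variance = m2,
    StandardDeviation = sqrt(m2),
    Skewness = skew,
    Kurtosis = kurt,
    IntensityEnergy = sum(x^2),
    HistEnergy = sum(p^2),
    HistEntropy = shannonEntropy(p),
    Uniformity = sum(valueProbs^2),
    RootMeanSquared = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    MedianAbsoluteDeviation = stats::median(abs(x - stats::median(x))),
    RobustMeanAbsoluteDeviation = robustMAD,
    InterquartileRange = p75 - p25,
    Sum = sum(x),
    Mode = mode,
    TrimmedMean = mean(x, trim = 0.05))
  pctNames <- c("Quantile0.025", paste0("Percentile", seq(5, 95, by = 5)),
                "Quantile0.975")
  out <- c(out, stats::setNames(pcts, pctNames))
  stopifnot(length(out) == 42L)
  out
}
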