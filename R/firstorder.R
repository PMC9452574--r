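#' First-order (histogram) features
#'
#' The 18 first-order statistics of the registry, computed on the raw
#' (unquantised) VOI intensities, except `Entropy` and `Uniformity` which
#' use the `ng`-level histogram probabilities and therefore carry the
#' grey-level dependence seen in the factorial analysis. Central moments
#' are population-style (divide by n); `Skewness = m3 / m2^1.5`;
#' `Kurtosis = m4 / m2^2` without the -3 excess correction, so a Gaussian
#' tends to 3. Percentiles interpolate linearly between order statistics.
#'
#' @param x Numeric vector of VOI intensities (at least one voxel).
#' @param ng Grey-level count for the histogram-based entries.
#' @param voxel_volume_mm3 Physical voxel volume; `TotalEnergy` is
#'   `Energy` scaled by it.
#' @return Named numeric vector of the 18 `firstorder_*` features, with a
#'   logical `degenerate` attribute (constant or single-voxel input).
#' @export
first_order_features <- function(x, ng, voxel_volume_mm3 = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1L) stop("first-order features need at least one voxel")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  degenerate <- n < 2L || m2 == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  in_core <- x >= qs[1] & x <= qs[4]
  rmad <- mean(abs(x[in_core] - mean(x[in_core])))

  # ng-level histogram probabilities over the VOI min-max range
  if (max(x) > min(x)) {
    lv <- pmin(floor(ng * (x - min(x)) / (max(x) - min(x))) + 1L, ng)
  } else {
    lv <- rep(1L, n)
  }
  p <- tabulate(lv, nbins = ng) / n
  p_pos <- p[p > 0]

  energy <- sum(x^2)
  out <- c(
    Energy = energy,
    TotalEnergy = energy * voxel_volume_mm3,
    Entropy = -sum(p_pos * log2(p_pos)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = qs[3] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  names(out) <- paste0("firstorder_", names(out))
  attr(out, "degenerate") <- degenerate
  out
}
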