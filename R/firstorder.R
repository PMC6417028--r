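FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "StandardDeviation", "Skewness", "Kurtosis", "Variance", "Uniformity"
)

#' First-order (histogram) features
#'
#' The 19 intensity-distribution statistics of the in-mask voxels. These are
#' position-free: any permutation of voxel locations leaves them unchanged.
#' `TotalEnergy` is `Energy` times the physical voxel volume in mm^3.
#' Percentiles use linear interpolation (type 7). `Entropy` and `Uniformity`
#' are computed on the discretized grey-level histogram (`n_bins` levels).
#' Variance, SD, skewness and kurtosis use population moments; kurtosis is
#' not excess-corrected. A constant region has `Skewness` and `Kurtosis`
#' flagged degenerate and set to 0.
#'
#' @param vol a [volume_image()].
#' @param mask an aligned [lesion_mask()].
#' @param n_bins grey levels for the histogram-based entropy/uniformity.
#' @return Named numeric vector of 19 features, with attribute `degenerate`.
#' @export
first_order_features <- function(vol, mask, n_bins = 32) {
  check_alignment(vol, mask)
  x <- vol$values[mask$values]
  n <- length(x)
  vv <- voxel_volume(vol$spacing)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdev <- sqrt(m2)
  degenerate <- m2 == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  # histogram over equal-width bins of the in-mask range
  if (degenerate) {
    p <- 1
  } else {
    w <- (max(x) - min(x)) / n_bins
    lev <- pmin(floor((x - min(x)) / w) + 1L, as.integer(n_bins))
    p <- tabulate(lev, n_bins) / n
    p <- p[p > 0]
  }
  out <- c(
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    Mean = mu,
    Median = stats::median(x),
    InterquartileRange = q[3] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sdev,
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2)
  )
  names(out) <- FIRSTORDER_NAMES
  attr(out, "degenerate") <- degenerate
  out
}
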