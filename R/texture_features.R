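GLCM_NAMES <- c(
  "Autocorrelation", "AverageIntensity", "GrayLevelIntensity",
  "ClusterProminence", "ClusterShade", "ClusterTendency", "Contrast",
  "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Dissimilarity", "Energy", "Entropy", "Homogeneity1",
  "Homogeneity2", "InformalMeasureOfCorrelation1",
  "InformalMeasureOfCorrelation2", "InverseDifferenceMoment",
  "InverseDifferenceMomentNormalized", "InverseDifference", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumVariance",
  "SumOfSquares"
)

GLRLM_NAMES <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "ShortRunEmphasis",
  "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis",
  "RunEntropy", "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
  "RunPercentage", "RunVariance"
)

GLSZM_NAMES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# 27 features from one normalized symmetric co-occurrence matrix.
# Degenerate matrix (no pairs): all 0. Zero-variance (single level):
# correlation-type features take 1 by convention, entropies and
# distance-type features 0.
glcm_features_single <- function(tm) {
  Ng <- tm$Ng
  P <- tm$normalized
  out <- stats::setNames(numeric(27), GLCM_NAMES)
  if (tm$degenerate) return(out)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)                 # == py by symmetry
  mu <- sum(seq_len(Ng) * px)
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  dif <- abs(i - j)
  psum <- vapply(2:(2 * Ng), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2 * Ng)
  pdiff <- vapply(0:(Ng - 1), function(k) sum(P[dif == k]), numeric(1))
  kd <- 0:(Ng - 1)
  DA <- sum(kd * pdiff)
  SA <- sum(ks * psum)
  HXY <- -sum(xlog2(P))
  pxi_pyj <- outer(px, px)
  HXY1 <- -sum(ifelse(pxi_pyj > 0, P * log2(pxi_pyj), 0))
  HXY2 <- -sum(xlog2(pxi_pyj))
  HX <- -sum(xlog2(px))
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1

  out["Autocorrelation"] <- sum(i * j * P)
  out["AverageIntensity"] <- mu
  out["GrayLevelIntensity"] <- sum((i - mu)^2 * P)
  out["ClusterProminence"] <- sum((i + j - 2 * mu)^4 * P)
  out["ClusterShade"] <- sum((i + j - 2 * mu)^3 * P)
  out["ClusterTendency"] <- sum((i + j - 2 * mu)^2 * P)
  out["Contrast"] <- sum((i - j)^2 * P)
  out["Correlation"] <- corr
  out["DifferenceAverage"] <- DA
  out["DifferenceEntropy"] <- -sum(xlog2(pdiff))
  out["DifferenceVariance"] <- sum((kd - DA)^2 * pdiff)
  out["Dissimilarity"] <- sum(dif * P)
  out["Energy"] <- sum(P^2)
  out["Entropy"] <- HXY
  out["Homogeneity1"] <- sum(P / (1 + dif))
  out["Homogeneity2"] <- sum(P / (1 + dif^2))
  out["InformalMeasureOfCorrelation1"] <- imc1
  out["InformalMeasureOfCorrelation2"] <- imc2
  out["InverseDifferenceMoment"] <- sum(P / (1 + dif^2))
  out["InverseDifferenceMomentNormalized"] <- sum(P / (1 + (dif / Ng)^2))
  out["InverseDifference"] <- sum(P / (1 + dif))
  out["InverseVariance"] <- sum(P[dif > 0] / dif[dif > 0]^2)
  out["MaximumProbability"] <- max(P)
  out["SumAverage"] <- SA
  out["SumEntropy"] <- -sum(xlog2(psum))
  out["SumVariance"] <- sum((ks - SA)^2 * psum)
  out["SumOfSquares"] <- sum((i - mu)^2 * P)
  out
}

#' Grey-level co-occurrence features
#'
#' The 27 co-occurrence statistics, each computed per direction from the
#' normalized symmetric matrix and arithmetically averaged over the 13 unique
#' 3-D directions at distance 1. `AverageIntensity` is the joint grey-level
#' average and `GrayLevelIntensity` the joint grey-level variance (interpretive
#' mappings for two non-standard names; the latter coincides with
#' `SumOfSquares`, and `Homogeneity1`/`InverseDifference` and
#' `Homogeneity2`/`InverseDifferenceMoment` coincide by construction).
#'
#' @param d a [discretize()]d ROI.
#' @param distance co-occurrence step in voxels.
#' @return Named numeric vector of 27 features with attribute `degenerate`.
#' @export
glcm_features <- function(d, distance = 1L) {
  dirs <- texture_directions()
  mats <- lapply(seq_len(nrow(dirs)), function(k)
    glcm_matrix(d, dirs[k, ], distance))
  per_dir <- lapply(mats, glcm_features_single)
  out <- Reduce(`+`, per_dir) / length(per_dir)
  attr(out, "degenerate") <- all(vapply(mats, `[[`, logical(1), "degenerate"))
  out
}

glrlm_features_single <- function(tm, n_voxels) {
  out <- stats::setNames(numeric(16), GLRLM_NAMES)
  if (tm$degenerate) return(out)
  P <- tm$counts
  Nr <- sum(P)
  Ng <- nrow(P); Lmax <- ncol(P)
  iv <- seq_len(Ng); lv <- seq_len(Lmax)
  gi <- rowSums(P); rl <- colSums(P)
  p <- P / Nr
  mu_i <- sum(iv * rowSums(p))
  mu_l <- sum(lv * colSums(p))
  i2 <- matrix(iv^2, Ng, Lmax)
  l2 <- matrix(lv^2, Ng, Lmax, byrow = TRUE)
  out["GrayLevelNonUniformity"] <- sum(gi^2) / Nr
  out["GrayLevelNonUniformityNormalized"] <- sum(gi^2) / Nr^2
  out["GrayLevelVariance"] <- sum(p * (matrix(iv, Ng, Lmax) - mu_i)^2)
  out["HighGrayLevelRunEmphasis"] <- sum(P * i2) / Nr
  out["LongRunEmphasis"] <- sum(P * l2) / Nr
  out["LongRunHighGrayLevelEmphasis"] <- sum(P * i2 * l2) / Nr
  out["LongRunLowGrayLevelEmphasis"] <- sum(P * l2 / i2) / Nr
  out["LowGrayLevelRunEmphasis"] <- sum(P / i2) / Nr
  out["ShortRunEmphasis"] <- sum(P / l2) / Nr
  out["ShortRunHighGrayLevelEmphasis"] <- sum(P * i2 / l2) / Nr
  out["ShortRunLowGrayLevelEmphasis"] <- sum(P / (i2 * l2)) / Nr
  out["RunEntropy"] <- -sum(xlog2(p))
  out["RunLengthNonUniformity"] <- sum(rl^2) / Nr
  out["RunLengthNonUniformityNormalized"] <- sum(rl^2) / Nr^2
  out["RunPercentage"] <- Nr / n_voxels
  out["RunVariance"] <- sum(p * (matrix(lv, Ng, Lmax, byrow = TRUE) - mu_l)^2)
  out
}

#' Grey-level run-length features
#'
#' The 16 run-length statistics, averaged over the 13 directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features with attribute `degenerate`.
#' @export
glrlm_features <- function(d) {
  n_vox <- sum(d$mask)
  dirs <- texture_directions()
  per_dir <- lapply(seq_len(nrow(dirs)), function(k)
    glrlm_features_single(glrlm_matrix(d, dirs[k, ]), n_vox))
  out <- Reduce(`+`, per_dir) / length(per_dir)
  attr(out, "degenerate") <- FALSE
  out
}

#' Grey-level size-zone features
#'
#' The 16 size-zone statistics from the single (direction-free) matrix of
#' 26-connected equal-level zones.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features with attribute `degenerate`.
#' @export
glszm_features <- function(d) {
  tm <- glszm_matrix(d)
  n_vox <- sum(d$mask)
  out <- stats::setNames(numeric(16), GLSZM_NAMES)
  if (tm$degenerate) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  P <- tm$counts
  Nz <- sum(P)
  Ng <- nrow(P); Smax <- ncol(P)
  iv <- seq_len(Ng); sv <- seq_len(Smax)
  gi <- rowSums(P); zs <- colSums(P)
  p <- P / Nz
  mu_i <- sum(iv * rowSums(p))
  mu_s <- sum(sv * colSums(p))
  i2 <- matrix(iv^2, Ng, Smax)
  s2 <- matrix(sv^2, Ng, Smax, byrow = TRUE)
  out["SmallAreaEmphasis"] <- sum(P / s2) / Nz
  out["LargeAreaEmphasis"] <- sum(P * s2) / Nz
  out["GrayLevelNonUniformity"] <- sum(gi^2) / Nz
  out["GrayLevelNonUniformityNormalized"] <- sum(gi^2) / Nz^2
  out["SizeZoneNonUniformity"] <- sum(zs^2) / Nz
  out["SizeZoneNonUniformityNormalized"] <- sum(zs^2) / Nz^2
  out["ZonePercentage"] <- Nz / n_vox
  out["GrayLevelVariance"] <- sum(p * (matrix(iv, Ng, Smax) - mu_i)^2)
  out["ZoneVariance"] <- sum(p * (matrix(sv, Ng, Smax, byrow = TRUE) - mu_s)^2)
  out["ZoneEntropy"] <- -sum(xlog2(p))
  out["LowGrayLevelZoneEmphasis"] <- sum(P / i2) / Nz
  out["HighGrayLevelZoneEmphasis"] <- sum(P * i2) / Nz
  out["SmallAreaLowGrayLevelEmphasis"] <- sum(P / (i2 * s2)) / Nz
  out["SmallAreaHighGrayLevelEmphasis"] <- sum(P * i2 / s2) / Nz
  out["LargeAreaLowGrayLevelEmphasis"] <- sum(P * s2 / i2) / Nz
  out["LargeAreaHighGrayLevelEmphasis"] <- sum(P * i2 * s2) / Nz
  attr(out, "degenerate") <- FALSE
  out
}
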