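#' Intensity normalization
#'
#' Z-score normalization of a whole volume, `f(x) = s * (x - mu) / sigma`,
#' where `mu` and `sigma` are the mean and population standard deviation of
#' all voxels and `s` is an optional scale. This removes scanner gain/offset
#' so that texture features become invariant to intensity calibration.
#'
#' The spread term is the standard deviation (not the variance): only then is
#' the output unit-variance, which is the evident intent of the z-score
#' formulation. Population rather than sample SD is used; at whole-volume
#' voxel counts the difference is negligible.
#'
#' @param vol a [volume_image()] with more than one distinct value.
#' @param s positive scale; the output SD.
#' @return A normalized `volume_image` with mean 0 and SD `s`.
#' @export
normalize_intensity <- function(vol, s = 1) {
  stopifnot(inherits(vol, "volume_image"))
  if (!is.numeric(s) || length(s) != 1L || s <= 0) stop("s must be a positive scalar")
  x <- vol$values
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    stop("constant volume: intensity spread is zero, cannot normalize")
  out <- vol
  out$values <- s * (x - mu) / sigma
  out
}

#' Grey-level discretization of a masked region
#'
#' Maps in-mask intensities to integer grey levels `1..n_bins` with
#' equal-width bins spanning the in-mask `[min, max]`; the maximum maps to
#' level `n_bins`. Because volumes are z-score normalized first, a fixed bin
#' count (rather than a fixed bin width) is the meaningful choice.
#'
#' @param vol a [volume_image()].
#' @param mask an aligned [lesion_mask()].
#' @param n_bins number of grey levels (>= 2).
#' @return An object of class `discretized_roi` with fields `levels` (integer
#'   array, `NA` outside the mask), `n_levels`, `bin_edges`, `mask`,
#'   `spacing`, and `degenerate` (`TRUE` for a constant region, which yields
#'   a single level with a warning).
#' @export
discretize <- function(vol, mask, n_bins = 32) {
  check_alignment(vol, mask)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2)
    stop("n_bins must be >= 2")
  n_bins <- as.integer(n_bins)
  m <- mask$values
  x <- vol$values[m]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim(vol$values))
  if (hi == lo) {
    warning("constant region of interest: single grey level (degenerate texture)")
    lev[m] <- 1L
    return(structure(list(levels = lev, n_levels = 1L,
                          bin_edges = c(lo, hi), mask = m,
                          spacing = vol$spacing, degenerate = TRUE),
                     class = "discretized_roi"))
  }
  w <- (hi - lo) / n_bins
  l <- pmin(floor((x - lo) / w) + 1L, n_bins)
  lev[m] <- as.integer(l)
  structure(list(levels = lev, n_levels = n_bins,
                 bin_edges = seq(lo, hi, length.out = n_bins + 1L), mask = m,
                 spacing = vol$spacing, degenerate = FALSE),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi: %d levels over %d voxels%s>\n",
              x$n_levels, sum(x$mask), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
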