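FILTER_NAMES <- c(
  "exponential", "square", "squareroot", "logarithm",
  "wavelet-LLL", "wavelet-LLH", "wavelet-LHL", "wavelet-LHH",
  "wavelet-HLL", "wavelet-HLH", "wavelet-HHL", "wavelet-HHH"
)

# Coiflet-1 analysis filters (orthonormal; low-pass sums to sqrt(2)).
COIF1_LO <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
              0.852572020212255, 0.337897662457809, -0.072732619512854)
COIF1_HI <- rev(COIF1_LO) * c(1, -1, 1, -1, 1, -1)

#' Pointwise intensity filters
#'
#' Sign-preserving strictly monotone maps rescaled to the input magnitude
#' range. With `M = max(abs(x))` over the volume:
#' square `sign(x) x^2 / M`; squareroot `sign(x) sqrt(|x| M)`;
#' logarithm `sign(x) M log(|x| + 1) / log(M + 1)`;
#' exponential `sign(x) ((M + 1)^(|x|/M) - 1)`.
#' Each maps 0 to 0 and +/-M to +/-M, so filtered volumes stay on the scale
#' of the (normalized) input.
#'
#' @param vol a [volume_image()] with at least one non-zero voxel.
#' @param kind one of `"exponential"`, `"square"`, `"squareroot"`,
#'   `"logarithm"`.
#' @return A filtered `volume_image`.
#' @export
apply_pointwise_filter <- function(vol, kind) {
  stopifnot(inherits(vol, "volume_image"))
  kind <- match.arg(kind, c("exponential", "square", "squareroot", "logarithm"))
  x <- vol$values
  M <- max(abs(x))
  if (M == 0) stop("all-zero volume: pointwise filter undefined (M = 0)")
  s <- sign(x); a <- abs(x)
  y <- switch(kind,
    square = s * a^2 / M,
    squareroot = s * sqrt(a * M),
    logarithm = s * M * log(a + 1) / log(M + 1),
    exponential = s * ((M + 1)^(a / M) - 1)
  )
  out <- vol
  out$values <- y
  out
}

# circular (periodic) convolution along one axis of a 3-D array via FFT;
# filter taps h are centered so a symmetric impulse stays centered
conv_axis_periodic <- function(x, h, axis) {
  d <- dim(x)
  n <- d[axis]
  if (n < length(h)) stop("volume axis shorter than the wavelet filter support")
  hp <- numeric(n)
  # place taps so that tap k multiplies sample (t + k - offset), offset
  # chosen near the filter center
  off <- floor(length(h) / 2)
  idx <- ((seq_along(h) - 1 - off) %% n) + 1
  for (k in seq_along(h)) hp[idx[k]] <- hp[idx[k]] + h[k]
  H <- stats::fft(hp)
  X <- apply(x, setdiff(1:3, axis), function(v) Re(stats::fft(stats::fft(v) * H,
                                                              inverse = TRUE)) / n)
  # apply() puts the looped axis first; move it back (axes order of the
  # intermediate array is (axis, other axes ascending))
  axes_order <- c(axis, setdiff(1:3, axis))
  aperm(array(X, dim = c(n, d[-axis])), order(axes_order))
}

#' Single-level 3-D wavelet filter bank
#'
#' Undecimated (stationary) separable Coiflet-1 decomposition with periodic
#' boundary handling. Each band applies a low-pass (L) or high-pass (H)
#' filter along the x, y, z axes in that letter order, and is returned on the
#' original grid so the lesion mask applies unchanged. For the undecimated
#' transform the filters are scaled by `1/sqrt(2)` per axis so the LLL band
#' has unit DC gain (it is a smoothed copy of the input) and all H-containing
#' bands annihilate constants.
#'
#' @param vol a [volume_image()]; every axis must be at least as long as the
#'   filter (6 taps).
#' @return Named list of 8 `volume_image` bands
#'   (`wavelet-LLL` ... `wavelet-HHH`).
#' @export
wavelet_bands <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  d <- dim(vol$values)
  if (any(d < length(COIF1_LO)))
    stop("volume smaller than the wavelet filter support (6 voxels per axis)")
  lo <- COIF1_LO / sqrt(2)
  hi <- COIF1_HI / sqrt(2)
  ax1 <- list(L = conv_axis_periodic(vol$values, lo, 1),
              H = conv_axis_periodic(vol$values, hi, 1))
  out <- list()
  for (b1 in c("L", "H")) {
    ax2 <- list(L = conv_axis_periodic(ax1[[b1]], lo, 2),
                H = conv_axis_periodic(ax1[[b1]], hi, 2))
    for (b2 in c("L", "H")) {
      for (b3 in c("L", "H")) {
        band <- conv_axis_periodic(ax2[[b2]], if (b3 == "L") lo else hi, 3)
        v <- vol
        v$values <- band
        out[[paste0("wavelet-", b1, b2, b3)]] <- v
      }
    }
  }
  out[c("wavelet-LLL", "wavelet-LLH", "wavelet-LHL", "wavelet-LHH",
        "wavelet-HLL", "wavelet-HLH", "wavelet-HHL", "wavelet-HHH")]
}

# Decimated orthonormal single-level DWT along each axis with periodic
# extension. Only used to verify energy conservation (Parseval) on dyadic
# grids; the feature pipeline uses the undecimated transform.
dwt3_decimated <- function(x) {
  step_axis <- function(arr, h, axis) {
    d <- dim(arr)
    n <- d[axis]
    if (n %% 2L != 0L) stop("decimated transform requires even axis lengths")
    y <- apply(arr, setdiff(1:3, axis), function(v) {
      vapply(seq(1, n, by = 2), function(t)
        sum(h * v[((t - 1 + seq_along(h) - 1) %% n) + 1]), numeric(1))
    })
    axes_order <- c(axis, setdiff(1:3, axis))
    aperm(array(y, dim = c(n / 2, d[-axis])), order(axes_order))
  }
  out <- list()
  for (b1 in c("L", "H")) {
    a1 <- step_axis(x, if (b1 == "L") COIF1_LO else COIF1_HI, 1)
    for (b2 in c("L", "H")) {
      a2 <- step_axis(a1, if (b2 == "L") COIF1_LO else COIF1_HI, 2)
      for (b3 in c("L", "H")) {
        out[[paste0(b1, b2, b3)]] <-
          step_axis(a2, if (b3 == "L") COIF1_LO else COIF1_HI, 3)
      }
    }
  }
  out
}

#' Apply the full 12-filter bank
#'
#' @param vol a [volume_image()].
#' @return Named list of exactly 12 `volume_image`s: the four pointwise
#'   filters and the eight wavelet bands.
#' @export
filter_bank <- function(vol) {
  out <- c(
    lapply(stats::setNames(nm = c("exponential", "square", "squareroot",
                                  "logarithm")),
           function(k) apply_pointwise_filter(vol, k)),
    wavelet_bands(vol)
  )
  stopifnot(identical(names(out), FILTER_NAMES))
  out
}
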