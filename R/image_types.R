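#' Imaging containers
#'
#' A `volume_image` is a 3-D scalar grid with physical voxel spacing (mm) and
#' a sequence tag; a `lesion_mask` is a binary 3-D grid with the same
#' geometry. Features never depend on the origin, only on spacing, so origin
#' and orientation metadata are carried through opaquely.
#'
#' @param values numeric 3-D array with finite entries.
#' @param spacing positive numeric vector of length 3, voxel spacing in mm.
#' @param sequence one of `"inphase"`, `"outphase"`, `"t2wi"`, `"dwi"`, or
#'   `"unknown"` for volumes outside the four-sequence protocol.
#' @param origin optional numeric length-3 offset, passed through unchanged.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), sequence = "unknown",
                         origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume values must be a 3-D array")
  if (any(dim(values) < 1L)) stop("volume grid is empty")
  if (!all(is.finite(values))) stop("volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  sequence <- match.arg(sequence, c("inphase", "outphase", "t2wi", "dwi", "unknown"))
  structure(
    list(values = values, spacing = spacing, sequence = sequence,
         origin = as.numeric(origin)),
    class = "volume_image"
  )
}

#' @param values binary (0/1 or logical) 3-D array; values strictly between 0
#'   and 1 are rejected, use [read_mask()] for >0.5 binarization of files.
#' @rdname volume_image
#' @export
lesion_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask values must be a 3-D array")
  if (is.logical(values)) {
    v <- values
  } else {
    if (!all(values %in% c(0, 1)))
      stop("mask must be strictly binary (multi-label masks are rejected)")
    v <- values > 0.5
  }
  if (!any(v)) stop("empty mask: no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  dim(v) <- dim(values)
  structure(
    list(values = v, spacing = spacing, origin = as.numeric(origin)),
    class = "lesion_mask"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image %s: %s voxels, spacing %s mm>\n",
              x$sequence, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask: %s voxels, %d foreground, spacing %s mm>\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Validate that a mask is aligned with a volume
#'
#' Grid shape and voxel spacing must match exactly; there is no silent
#' resampling anywhere in the pipeline.
#'
#' @param vol a [volume_image()].
#' @param mask a [lesion_mask()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_alignment <- function(vol, mask) {
  stopifnot(inherits(vol, "volume_image"), inherits(mask, "lesion_mask"))
  if (!identical(dim(vol$values), dim(mask$values)))
    stop(sprintf("alignment error: volume grid %s differs from mask grid %s",
                 paste(dim(vol$values), collapse = "x"),
                 paste(dim(mask$values), collapse = "x")))
  if (!isTRUE(all.equal(vol$spacing, mask$spacing, tolerance = 1e-8)))
    stop("alignment error: volume and mask spacing differ (no silent resampling)")
  invisible(TRUE)
}

voxel_volume <- function(spacing) prod(spacing)
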