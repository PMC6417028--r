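# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader ships with this package's dependency set, so the format is
# handled directly: fixed 348-byte header, voxel data at vox_offset. Only the
# fields the pipeline needs are interpreted (dim, datatype, pixdim,
# scl_slope/inter); orientation fields are passed through opaquely on read
# and written as a plain identity-like header on write. Supported datatypes:
# uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64).

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  # gzfile reads plain files transparently; for writing pick by extension
  if (grepl("w", open)) {
    if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
  } else {
    gzfile(path, open)
  }
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    endian <- "big"
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  rd <- function(bytes, what, size, n = 1L)
    readBin(bytes, what, n = n, size = size, endian = endian)
  dims <- rd(hdr_raw[41:56], "integer", 2L, 8L)
  datatype <- rd(hdr_raw[71:72], "integer", 2L)
  pixdim <- rd(hdr_raw[77:108], "double", 4L, 8L)
  vox_offset <- rd(hdr_raw[109:112], "double", 4L)
  scl_slope <- rd(hdr_raw[113:116], "double", 4L)
  scl_inter <- rd(hdr_raw[117:120], "double", 4L)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[2:4] < 1L))
    stop("volume is not 3-D: ", path)
  if (ndim > 3L && any(dims[5:(ndim + 1)] > 1L))
    stop("volume is not 3-D (extra non-singleton dimensions): ", path)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, " in ", path)
  nvox <- prod(dims[2:4])
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated voxel data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (any(!is.finite(vals))) stop("NaN or infinite voxels in ", path)
  dim(vals) <- dims[2:4]
  list(values = vals, spacing = pixdim[2:4],
       origin = c(0, 0, 0), datatype = datatype)
}

write_nifti <- function(values, spacing, path, datatype = 16L) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wr_i <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wr_d <- function(x, size) writeBin(as.double(x), con, size = size, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)
  wr_i(348L, 4L)                       # sizeof_hdr
  wr_raw(36L)                          # data_type, db_name, extents, session_error, regular, dim_info
  wr_i(c(3L, dim(values), 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wr_raw(14L)                          # intent_p1..p3, intent_code
  wr_i(datatype, 2L)                   # datatype
  wr_i(dt$bitpix, 2L)                  # bitpix
  wr_i(0L, 2L)                         # slice_start
  wr_d(c(1, spacing, 1, 1, 1, 1), 4L)  # pixdim[8]
  wr_d(352, 4L)                        # vox_offset
  wr_d(1, 4L)                          # scl_slope
  wr_d(0, 4L)                          # scl_inter
  wr_raw(4L)                           # slice_end (short), slice_code, xyzt_units
  wr_d(c(0, 0, 0), 4L)                 # cal_max, cal_min, slice_duration
  wr_d(0, 4L)                          # toffset
  wr_i(c(0L, 0L), 4L)                  # glmax, glmin
  wr_raw(104L)                         # descrip[80] + aux_file[24]
  wr_i(c(0L, 1L), 2L)                  # qform_code, sform_code
  wr_d(rep(0, 6), 4L)                  # quatern b,c,d + qoffset x,y,z
  wr_d(c(spacing[1], 0, 0, 0), 4L)     # srow_x
  wr_d(c(0, spacing[2], 0, 0), 4L)     # srow_y
  wr_d(c(0, 0, spacing[3], 0), 4L)     # srow_z
  wr_raw(16L)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  wr_raw(4L)                           # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(values), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(values), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read and write volumes and masks (NIfTI-1)
#'
#' Volumes are written as float64 (exact round trips), masks as uint8. On read, masks are
#' binarized at > 0.5 and an all-background mask is an error. Voxel spacing is
#' taken from the header `pixdim`.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param sequence sequence tag to attach to the volume.
#' @return [read_volume()] a `volume_image`; [read_mask()] a `lesion_mask`.
#' @export
read_volume <- function(path, sequence = "unknown") {
  nf <- read_nifti(path)
  volume_image(nf$values, spacing = nf$spacing, sequence = sequence,
               origin = nf$origin)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  nf <- read_nifti(path)
  v <- nf$values > 0.5
  if (!any(v)) stop("empty mask in ", path)
  dim(v) <- dim(nf$values)
  lesion_mask(v, spacing = nf$spacing, origin = nf$origin)
}

#' @param vol a `volume_image` to write (float64).
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  write_nifti(vol$values, vol$spacing, path, datatype = 64L)
}

#' @param mask a `lesion_mask` to write (uint8).
#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_nifti(mask$values + 0L, mask$spacing, path, datatype = 2L)
}
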