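# Minimal single-file NIfTI-1 I/O.
#
# No NIfTI reader ships with the supported dependency set, so the small slice
# of the format this package needs is implemented here: single-file .nii /
# .nii.gz, little-endian, 3D, scalar datatypes, spacing carried in pixdim and
# an axis-aligned sform. NIfTI stores x fastest; package arrays are (z,y,x)
# with z fastest, so data are transposed on the way in and out.

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D array as a NIfTI-1 file
#'
#' Writes a single-file NIfTI-1 image (`.nii`, or gzip-compressed when the
#' path ends in `.nii.gz`). Attenuation volumes are stored as int16, masks as
#' uint8. Spacing (mm) goes into `pixdim` and an axis-aligned `sform`.
#'
#' @param x an [attenuation_volume()], a [lung_mask()], or a bare 3D array
#'   (axis order `(z, y, x)`).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel spacing `(z, y, x)` in mm; taken from `x` when it is a
#'   volume and ignored otherwise unless given.
#' @param datatype NIfTI datatype code: 4 (int16, default for HU) or
#'   2 (uint8, default for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = NULL, datatype = NULL) {
  if (inherits(x, "attenuation_volume")) {
    spacing <- spacing %||% x$spacing
    datatype <- datatype %||% 4L
    arr <- x$voxels
  } else if (inherits(x, "lung_mask")) {
    spacing <- spacing %||% c(1, 1, 1)
    datatype <- datatype %||% 2L
    arr <- x$voxels + 0L
  } else {
    spacing <- spacing %||% c(1, 1, 1)
    datatype <- datatype %||% 4L
    arr <- x
  }
  if (length(dim(arr)) != 3L)
    stop_pedct("only 3D images are supported", "pedct_nifti_error")
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop_pedct(paste("unsupported NIfTI datatype", datatype),
               "pedct_nifti_error")

  # package order (z,y,x) -> NIfTI order (x,y,z), x fastest
  arr <- aperm(arr, c(3, 2, 1))
  dims <- dim(arr)
  sp <- rev(as.numeric(spacing))

  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348L, 4)                         # sizeof_hdr
  wc("", 10); wc("", 18)              # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2)                # extents, session_error
  wc("r", 1); wc("", 1)               # regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)           # intent_p1..3, intent_code
  wi(datatype, 2); wi(8L * dt$size, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(c(1, sp, 1, 1, 1, 1))            # pixdim[8]
  wf(352)                             # vox_offset
  wf(1); wf(0)                        # scl_slope, scl_inter
  wi(0L, 2); wc("", 1)                # slice_end, slice_code
  writeBin(as.raw(2L), con)           # xyzt_units: mm
  wf(c(0, 0, 0, 0))                   # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                    # glmax, glmin
  wc("pedlungct", 80); wc("", 24)     # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))      # quatern, qoffset
  wf(c(sp[1], 0, 0, 0))               # srow_x
  wf(c(0, sp[2], 0, 0))               # srow_y
  wf(c(0, 0, sp[3], 0))               # srow_z
  wc("", 16); wc("n+1", 4)            # intent_name, magic
  writeBin(raw(4), con)               # extension flag

  if (dt$what == "integer") {
    v <- as.integer(arr)
    if (dt$size == 1L && !dt$signed) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(v, con, size = dt$size, endian = "little")
    }
  } else {
    writeBin(as.numeric(arr), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Reads a little-endian single-file NIfTI-1 image written by [write_nifti()]
#' or by other tools, returning the array in this package's `(z, y, x)` axis
#' order with spacing from `pixdim`.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as one of `"volume"` (an [attenuation_volume()]), `"mask"`
#'   (a [lung_mask()]; nonzero voxels are TRUE) or `"array"`.
#' @return See `as`.
#' @export
read_nifti <- function(path, as = c("volume", "mask", "array")) {
  as <- match.arg(as)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop_pedct("truncated NIfTI header", "pedct_nifti_error")
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + n * size)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + n * 4L)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L)
    stop_pedct("not a little-endian NIfTI-1 file", "pedct_nifti_error")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_pedct("bad NIfTI magic", "pedct_nifti_error")
  dim8 <- ri(40L, 2L, 8L)
  ndim <- dim8[1]
  if (ndim < 3L)
    stop_pedct("only 3D images are supported", "pedct_nifti_error")
  if (ndim > 3L && any(dim8[seq(5L, ndim + 1L)] > 1L))
    stop_pedct("only 3D images are supported", "pedct_nifti_error")
  dims <- dim8[2:4]
  datatype <- ri(70L, 2L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop_pedct(paste("unsupported NIfTI datatype", datatype),
               "pedct_nifti_error")
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  if (dt$what == "integer" && dt$size == 1L && !dt$signed) {
    v <- as.integer(readBin(con, "raw", n = n))
  } else {
    v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                 endian = "little")
  }
  if (length(v) < n)
    stop_pedct("truncated NIfTI data", "pedct_nifti_error")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  arr <- array(v, dim = dims)
  arr <- aperm(arr, c(3, 2, 1))       # NIfTI (x,y,z) -> package (z,y,x)
  spacing <- rev(pixdim[2:4])
  switch(as,
         array = arr,
         mask = lung_mask(arr != 0),
         volume = attenuation_volume(round_half_away(arr), spacing))
}
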