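# Minimal NIfTI-1 reader/writer (uncompressed single-file .nii).
#
# No NIfTI-capable R package is available in the deployment environment, so
# the subset of the format the pipeline needs is implemented here: 3-D/4-D
# volumes, datatypes uint8/int16/int32/float32/float64, scl_slope/scl_inter
# scaling, sform affine, both endiannesses on read. Written files carry a
# diagonal sform built from the voxel size (sform_code = 1) and are readable
# by nibabel/FSL/SPM.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE))

#' Read a NIfTI-1 image
#'
#' @param path path to an uncompressed `.nii` file.
#' @return list with `data` (numeric array, scl slope/intercept applied),
#'   `dim`, `voxel_mm` (pixdim of the spatial axes), `affine` (4 x 4 sform,
#'   or a diagonal fallback built from pixdim), `tr_s` (pixdim[4] for 4-D
#'   images, else NA).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0)
    sz <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (sz != 348L)
      stop("read_nifti: not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L || ndim > 4L)
    stop("read_nifti: only 3-D and 4-D images supported, got ndim = ", ndim)
  d <- dims[2:(1 + ndim)]
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("read_nifti: unsupported datatype code ", datatype)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 254)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 280)
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("read_nifti: bad magic string")
  n_vox <- prod(d)
  seek(con, max(vox_offset, 352))
  raw_data <- readBin(con, dt$what, n = n_vox, size = dt$size,
                      signed = dt$signed, endian = endian)
  if (length(raw_data) < n_vox)
    stop("read_nifti: truncated data section (expected ", n_vox,
         " voxels, got ", length(raw_data), "): ", path)
  data <- as.numeric(raw_data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(pixdim[2:4], 1))
  list(data = array(data, dim = d), dim = d,
       voxel_mm = abs(pixdim[2:4]),
       affine = affine,
       tr_s = if (ndim == 4L) pixdim[5] else NA_real_)
}

#' Write a NIfTI-1 image
#'
#' @param data 3-D or 4-D numeric array.
#' @param path output path (`.nii`, uncompressed).
#' @param voxel_mm voxel size in mm (length 3).
#' @param tr_s repetition time in seconds (stored in pixdim[4] for 4-D data).
#' @param datatype `"float32"` (default), `"float64"`, `"int16"` or
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_mm = c(1, 1, 1), tr_s = 0,
                        datatype = "float32") {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("write_nifti: data must be a 3-D or 4-D array")
  code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L,
                 uint8 = 2L, stop("write_nifti: unsupported datatype"))
  size <- switch(datatype, float32 = 4L, float64 = 8L, int16 = 2L, uint8 = 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                             # sizeof_hdr
  writeBin(raw(36), con)                  # data_type, db_name, extents, ...
  dims <- c(length(d), d, rep(1L, 7 - length(d)))
  wi(dims, 2)                             # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)               # intent_p1..p3, intent_code
  wi(code, 2); wi(size * 8L, 2)           # datatype, bitpix
  wi(0L, 2)                               # slice_start
  pixdim <- c(1, voxel_mm, if (length(d) == 4L) tr_s else 0, 0, 0, 0)
  wf(pixdim)                              # pixdim[8]
  wf(352)                                 # vox_offset
  wf(1); wf(0)                            # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)        # slice_end, slice_code + xyzt_units
  seek(con, 123); writeBin(as.raw(10L), con)  # xyzt_units: mm | sec
  seek(con, 124)
  wf(c(0, 0, 0))                          # cal_max, cal_min, slice_duration
  wf(0)                                   # toffset
  wi(c(0L, 0L), 4)                        # glmax, glmin
  writeBin(raw(80 + 24), con)             # descrip, aux_file
  wi(0L, 2)                               # qform_code
  wi(1L, 2)                               # sform_code
  wf(rep(0, 6))                           # quaternion b,c,d + offsets
  wf(c(voxel_mm[1], 0, 0, 0))             # srow_x
  wf(c(0, voxel_mm[2], 0, 0))             # srow_y
  wf(c(0, 0, voxel_mm[3], 0))             # srow_z
  writeBin(raw(16), con)                  # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)  # magic
  writeBin(raw(4), con)                   # extension flag
  vals <- as.numeric(data)
  if (datatype %in% c("int16", "uint8")) {
    writeBin(as.integer(round(vals)), con, size = size, endian = "little")
  } else {
    writeBin(vals, con, size = size, endian = "little")
  }
  invisible(path)
}
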