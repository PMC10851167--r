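# Minimal NIfTI-1 I/O.
#
# The pre-installed R stack has no NIfTI package, so the pipeline carries a
# small single-file reader/writer: uncompressed .nii and gzipped .nii.gz,
# little-endian, 3-D images, datatypes uint8 / int16 / int32 / float32 /
# float64, scl_slope/scl_inter honoured on read. This is deliberately not a
# general neuroimaging I/O layer.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3-D array as a NIfTI-1 image
#'
#' @param data numeric 3-D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing_mm numeric length-3 voxel size in millimetres.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing_mm = c(1, 1, 1),
                        datatype = "float32") {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop_mdafm("unsupported NIfTI datatype '%s'", datatype))
  dt <- NIFTI_DTYPES[[as.character(code)]]
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wchr <- function(n) writeBin(raw(n), con)
  wint(348L, 4)                      # sizeof_hdr
  wchr(10); wchr(18)                 # data_type, db_name
  wint(0L, 4); wint(0L, 2); wchr(2)  # extents, session_error, regular+dim_info
  wint(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)        # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2)      # intent_p1-3, intent_code
  wint(code, 2); wint(dt$bitpix, 2); wint(0L, 2)   # datatype, bitpix, slice_start
  wflt(c(0, spacing_mm, 0, 0, 0, 0))               # pixdim[8]
  wflt(352); wflt(1); wflt(0)        # vox_offset, scl_slope, scl_inter
  wint(0L, 2); wchr(2)               # slice_end, slice_code + xyzt_units
  wflt(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4)                 # glmax, glmin
  wchr(80); wchr(24)                 # descrip, aux_file
  wint(c(0L, 1L), 2)                 # qform_code, sform_code
  wflt(c(0, 0, 0, 0, 0, 0))          # quatern, qoffset
  wflt(c(spacing_mm[1], 0, 0, 0))    # srow_x
  wflt(c(0, spacing_mm[2], 0, 0))    # srow_y
  wflt(c(0, 0, spacing_mm[3], 0))    # srow_z
  wchr(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)       # magic
  wchr(4)                            # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 image written by [write_nifti()] or compatible tools
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3-D array), `spacing_mm` (length-3), `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_mdafm("no such NIfTI file: %s", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_mdafm("truncated NIfTI header in %s", path)
  rint <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  rflt <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4L,
            endian = "little")
  if (rint(0, 4) != 348L)
    stop_mdafm("%s: not little-endian NIfTI-1 (sizeof_hdr != 348)", path)
  dims <- rint(40, 2, 8)
  ndim <- dims[1]
  if (ndim < 3L) dims <- c(dims[1], dims[2:(ndim + 1)], rep(1L, 3 - ndim))
  shape <- dims[2:4]
  code <- rint(70, 2)
  dt <- NIFTI_DTYPES[[as.character(code)]]
  if (is.null(dt)) stop_mdafm("%s: unsupported NIfTI datatype code %d", path, code)
  pixdim <- rflt(76, 8)
  vox_offset <- rflt(108)
  scl_slope <- rflt(112); scl_inter <- rflt(116)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = "little",
                  signed = dt$signed)
  if (length(vals) != n_vox) stop_mdafm("%s: truncated voxel data", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(as.numeric(vals), dim = shape),
       spacing_mm = abs(pixdim[2:4]),
       datatype = code)
}
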