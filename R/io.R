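#' Write an array as an uncompressed NIfTI-1 file
#'
#' Minimal single-file NIfTI-1 writer (little-endian, float32 or float64,
#' up to 4 dimensions, sform affine `diag(pixdim)`).  Sufficient for the
#' image interchange this package needs; files are readable by standard
#' NIfTI tools (e.g. nibabel).
#'
#' @param img numeric array with 2 to 4 dimensions.
#' @param path output path (`.nii`).
#' @param pixdim voxel spacing per dimension (mm), recycled to length 3.
#' @param datatype `"float32"` or `"float64"`.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1), datatype = "float32") {
  d <- dim(img)
  if (is.null(d) || length(d) < 2L || length(d) > 4L) {
    stopf("write_nifti supports 2- to 4-dimensional arrays")
  }
  pixdim <- rep_len(as.numeric(pixdim), 3)
  dim8 <- rep(1L, 8); dim8[1] <- length(d); dim8[seq_along(d) + 1L] <- d
  dt <- match.arg(datatype, c("float32", "float64"))
  code <- if (dt == "float32") 16L else 64L
  bitpix <- if (dt == "float32") 32L else 64L

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(dim8, 2)                                   # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(code, 2); wi(bitpix, 2); wi(0L, 2)         # datatype, bitpix, slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))                  # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)              # slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip[80] + aux_file[24]
  wi(0L, 2); wi(1L, 2)                          # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                                 # quatern b,c,d, qoffset x,y,z
  wf(c(pixdim[1], 0, 0, 0))                     # srow_x
  wf(c(0, pixdim[2], 0, 0))                     # srow_y
  wf(c(0, 0, pixdim[3], 0))                     # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(img), con,
           size = if (dt == "float32") 4 else 8, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Counterpart of [write_nifti()]: little-endian single-file NIfTI-1 with
#' float32, float64, int16 or int32 data.
#'
#' @param path `.nii` file.
#' @return numeric array with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348L) stopf("%s is not a little-endian NIfTI-1 file", path)
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  d <- dim8[seq_len(nd) + 1L]
  code <- ri(70, 2)
  pixdim <- rf(76, 8)[2:4]
  vox_offset <- rf(108)
  n <- prod(d)
  seek(con, vox_offset)
  data <- switch(as.character(code),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    "4"  = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = n, size = 4, endian = "little"),
    stopf("unsupported NIfTI datatype code %d in %s", code, path))
  out <- array(data, d)
  attr(out, "pixdim") <- pixdim
  out
}

#' Write a report as JSON
#'
#' Full-precision (`digits = NA`), auto-unboxed, pretty-printed JSON;
#' byte-identical across runs for identical inputs.
#'
#' @param x named list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Loads a YAML file and merges it over [experiment_config()] defaults;
#' nested fields may be given partially.
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  experiment_config(yaml::read_yaml(path))
}
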