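# Minimal NIfTI-1 single-file (.nii / .nii.gz) input/output.
#
# Only the subset of the format the pipeline needs is implemented: 3D/4D
# volumes, little-endian, datatypes uint8 / int16 / int32 / float32 / float64,
# sform affine. Scaling (scl_slope/scl_inter) is applied on read.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D volume as NIfTI-1
#'
#' @param data numeric or logical array with 3 or 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-mm matrix (stored as the sform).
#' @param dtype storage type: one of `"float64"` (default for numeric data,
#'   giving bit-exact round trips), `"float32"`, `"int32"`, `"int16"`,
#'   `"uint8"` (default for logical data).
#' @param pixdim voxel sizes; defaults to the column norms of `affine`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), dtype = NULL, pixdim = NULL) {
  if (is.logical(data)) {
    dtype <- dtype %||% "uint8"
    storage.mode(data) <- "integer"
  }
  dtype <- dtype %||% "float64"
  dt <- NIFTI_DTYPES[[dtype]]
  if (is.null(dt)) stop("unsupported dtype: ", dtype)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("data must be a 3D or 4D array")
  if (!is.matrix(affine) || any(dim(affine) != 4L)) stop("affine must be 4x4")
  dims <- dim(data)
  if (is.null(pixdim)) pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                                   # sizeof_hdr
  wb(raw(36L), 1L)                               # data_type..regular, dim_info
  dimv <- integer(8); dimv[1] <- nd; dimv[seq_len(nd) + 1L] <- dims
  dimv[dimv == 0L] <- 1L
  wb(as.integer(dimv), 2L)                       # dim[8]
  wb(c(0, 0, 0), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(dt$code, 2L); wb(dt$bitpix, 2L); wb(0L, 2L) # datatype, bitpix, slice_start
  pdv <- rep(1, 8)
  pdv[1L + seq_along(pixdim)] <- pixdim
  wb(as.double(pdv[1:8]), 4L)                    # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  wb(0L, 2L); wb(raw(2L), 1L)                    # slice_end, slice_code+xyzt
  wb(c(0, 0, 0, 0), 4L)                          # cal_max, cal_min, slice_dur, toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  wb(raw(80L + 24L), 1L)                         # descrip, aux_file
  wb(c(0L, 2L), 2L)                              # qform_code, sform_code=2
  wb(rep(0, 6), 4L)                              # quaternion + qoffset
  wb(as.double(t(affine[1:3, ])), 4L)            # srow_x/y/z
  wb(raw(16L), 1L)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  wb(raw(4L), 1L)                                # header padding to 352
  if (dt$what == "integer") {
    wb(as.integer(data), dt$size)
  } else if (dtype == "float32") {
    writeBin(as.double(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array), `affine` (4x4), `dtype`, `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  rb <- function(n, size, what = "integer", signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI header: file too short")
  rd <- function(off, n, size, what = "integer", signed = TRUE)
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = "little", signed = signed)
  if (rd(0L, 1L, 4L) != 348L) stop("malformed NIfTI header: bad sizeof_hdr")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI header: bad magic")
  dimv <- rd(40L, 8L, 2L)
  nd <- dimv[1]
  if (nd < 1L || nd > 7L) stop("malformed NIfTI header: bad ndim")
  dims <- dimv[1 + seq_len(nd)]
  dt_code <- rd(70L, 1L, 2L)
  dt_name <- names(Filter(function(d) d$code == dt_code, NIFTI_DTYPES))
  if (length(dt_name) == 0L) stop("unsupported NIfTI datatype code: ", dt_code)
  dt <- NIFTI_DTYPES[[dt_name]]
  pixdim <- rd(76L, 8L, 4L, "double")[2:4]
  vox_offset <- rd(108L, 1L, 4L, "double")
  scl_slope <- rd(112L, 1L, 4L, "double")
  scl_inter <- rd(116L, 1L, 4L, "double")
  sform_code <- rd(254L, 1L, 2L)
  if (sform_code > 0L) {
    srow <- matrix(rd(280L, 12L, 4L, "double"), nrow = 3L, byrow = TRUE)
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim, 1))
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- rb(n, dt$size, dt$what, signed = dt$signed)
  if (length(vals) < n) stop("malformed NIfTI file: truncated data")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), affine = affine,
       dtype = dt_name, pixdim = pixdim)
}
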