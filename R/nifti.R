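# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only what a CT volumetry pipeline needs: 3-D grids, sform/qform affines,
# datatypes uint8/int16/int32/float32/float64, scl slope/intercept.

NIFTI_HDR_SIZE <- 348L

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into a
#' [ct_volume()]. The world affine is taken from the sform when
#' `sform_code > 0`, else from the qform, else from `pixdim`.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_asym("io", paste("file not found:", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE) stop_asym("io", "truncated NIfTI header")
  endian <- "little"
  szh <- readBin(raw_hdr[1:4], "integer", 1, 4, endian = endian)
  if (szh != NIFTI_HDR_SIZE) {
    endian <- "big"
    szh <- readBin(raw_hdr[1:4], "integer", 1, 4, endian = endian)
    if (szh != NIFTI_HDR_SIZE) stop_asym("io", "not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd <- function(off, what, n, size) {
    readBin(raw_hdr[(off + 1):(off + n * size)], what, n, size, signed = TRUE,
            endian = endian)
  }
  dim8 <- rd(40, "integer", 8, 2)
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  quatern <- rd(256, "numeric", 3, 4)
  qoffset <- rd(268, "numeric", 3, 4)
  srow <- rbind(rd(280, "numeric", 4, 4), rd(296, "numeric", 4, 4),
                rd(312, "numeric", 4, 4))
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_asym("io", "unsupported NIfTI magic")
  ndim <- dim8[1]
  if (ndim < 3) stop_asym("io", "expected a 3-D image")
  dm <- dim8[2:4]
  nvox <- prod(dm)
  if (ndim >= 4 && prod(pmax(dim8[5:(1 + ndim)], 1)) > 1)
    stop_asym("io", "4-D+ images not supported")
  # skip to data
  skip <- vox_offset - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", nvox, 1, signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", nvox, 2, signed = TRUE, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", nvox, 4, signed = TRUE, endian = endian)),
    "16" = readBin(con, "numeric", nvox, 4, endian = endian),
    "64" = readBin(con, "numeric", nvox, 8, endian = endian),
    stop_asym("io", paste("unsupported NIfTI datatype", datatype)))
  if (length(vals) != nvox) stop_asym("io", "truncated NIfTI data")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- if (sform_code > 0) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    qform_affine(quatern, qoffset, pixdim)
  } else {
    a <- diag(c(pixdim[2:4], 1))
    a
  }
  ct_volume(array(vals, dim = dm), spacing = abs(pixdim[2:4]), affine = affine)
}

qform_affine <- function(quatern, qoffset, pixdim) {
  b <- quatern[1]; c_ <- quatern[2]; d <- quatern[3]
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
    2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
  ), 3, 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  R <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(R, qoffset), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 volume
#'
#' Writes a [ct_volume()] as single-file NIfTI-1 (float32, sform affine).
#' Gzip compression is chosen from the file extension.
#'
#' @param volume a [ct_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  dm <- dim(volume$voxels)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wb(NIFTI_HDR_SIZE, 4)                       # sizeof_hdr
  wraw(34)                                    # data_type, db_name, extents, ...
  writeBin(charToRaw("r"), con)               # regular
  wraw(1)                                     # dim_info
  wb(as.integer(c(3, dm, 1, 1, 1, 1)), 2)     # dim[8]
  wb(c(0, 0, 0), 4)                           # intent_p1..3
  wb(0L, 2)                                   # intent_code
  wb(16L, 2)                                  # datatype = float32
  wb(32L, 2)                                  # bitpix
  wb(0L, 2)                                   # slice_start
  wb(c(1, volume$spacing, 0, 0, 0, 0), 4)     # pixdim[8]
  wb(352, 4)                                  # vox_offset
  wb(c(1, 0), 4)                              # scl_slope, scl_inter
  wb(0L, 2); wraw(2)                          # slice_end, slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4)                        # cal_max/min, slice_duration, toffset
  wb(c(0L, 0L), 4)                            # glmax, glmin
  desc <- charToRaw("asymstroke")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip[80]
  wraw(24)                                    # aux_file
  wb(0L, 2)                                   # qform_code
  wb(1L, 2)                                   # sform_code
  wb(c(0, 0, 0, 0, 0, 0), 4)                  # quatern, qoffset
  wb(as.numeric(t(volume$affine[1:3, ])), 4)  # srow_x/y/z
  wraw(16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                                     # extension flag
  wb(as.numeric(volume$voxels), 4)
  invisible(path)
}
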