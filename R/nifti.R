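## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## No NIfTI package is available in this environment, and the format's
## single-file variant is a fixed 348-byte header + raw voxels, which base R
## handles directly.  Supported datatypes: uint8 (2), int16 (4), int32 (8),
## float32 (16), float64 (64).  scl_slope/scl_inter are honored on read.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L,
                  float32 = 32L, float64 = 64L)

nii_con <- function(file, open) {
  if (grepl("\\.gz$", file)) gzfile(file, open) else file(file, open)
}

#' Write a NIfTI-1 volume
#'
#' @param data 2-D or 3-D numeric array.
#' @param file Path ending in `.nii` or `.nii.gz`.
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @param pixdim Voxel spacing in mm per dimension.
#' @return `file`, invisibly.
#' @export
write_nifti <- function(data, file, datatype = "float32",
                        pixdim = c(1, 1, 1)) {
  stopifnot(datatype %in% names(NIFTI_DT))
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  nd <- length(dims)
  stopifnot(nd <= 7L)
  dim_field <- as.integer(c(nd, dims, rep(1L, 7L - nd)))
  con <- nii_con(file, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused / dim_info
  writeBin(c(dim_field), con, size = 2)               # dim[0..7]
  writeBin(raw(14), con)                              # intent_p1..3, intent_code
  writeBin(as.integer(NIFTI_DT[[datatype]]), con, size = 2)
  writeBin(as.integer(NIFTI_BITPIX[[datatype]]), con, size = 2)
  writeBin(0L, con, size = 2)                         # slice_start
  pd <- c(1, pixdim, rep(1, 7 - length(pixdim)))[1:8]
  writeBin(as.numeric(pd), con, size = 4)             # pixdim[0..7]
  writeBin(352, con, size = 4)                        # vox_offset (float!)
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(raw(228), con)                             # rest of header
  writeBin(raw(4), con)                               # extension flag
  v <- as.vector(data)
  sz <- NIFTI_BITPIX[[datatype]] / 8L
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(v), con, size = sz)
  } else {
    writeBin(as.integer(round(v)), con, size = sz)
  }
  invisible(file)
}

#' Read a NIfTI-1 volume
#'
#' @param file Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `pixdim` (spacing of the used dims) and
#'   `datatype`.
#' @export
read_nifti <- function(file) {
  con <- nii_con(file, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1, size = 4)
  if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", file)
  dimf <- readBin(hdr[41:56], "integer", 8, size = 2)
  nd <- dimf[1]
  dims <- dimf[2:(1 + nd)]
  datatype_code <- readBin(hdr[71:72], "integer", 1, size = 2)
  dt <- names(NIFTI_DT)[match(datatype_code, unlist(NIFTI_DT))]
  if (is.na(dt)) stop("unsupported NIfTI datatype code ", datatype_code)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4)[2:(1 + nd)]
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4)
  scl <- readBin(hdr[113:120], "numeric", 2, size = 4)
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(dims)
  sz <- NIFTI_BITPIX[[dt]] / 8L
  v <- if (dt %in% c("float32", "float64")) {
    readBin(con, "numeric", n, size = sz)
  } else if (dt == "uint8") {
    as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n, size = sz))
  }
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) v <- v * scl[1] + scl[2]
  array(v, dims) -> a
  list(data = a, pixdim = pixdim, datatype = dt)
}
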