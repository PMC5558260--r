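# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O, float32, no
# orientation metadata beyond isotropic pixdim. Implemented here because no
# NIfTI-capable R package is available in the runtime environment.

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param vol numeric 3D array.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param voxel_size_mm isotropic voxel size stored in `pixdim`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size_mm = 1.0) {
  stopifnot(length(dim(vol)) == 3L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36L), con)                       # data_type..dim_info
  wi(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2)        # dim[8]
  wi(rep(0L, 7L), 2)                            # intent_p1..intent_code
  wi(16L, 2)                                    # datatype = float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, rep(voxel_size_mm, 3), 1, 1, 1, 1))   # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2L), con)             # slice_end, slice_code, xyzt
  wf(c(0, 0))                                   # cal_max, cal_min
  wf(c(0, 0)); wi(c(0L, 0L), 4)                 # slice_duration..glmin
  writeBin(raw(104L), con)                      # descrip + aux_file
  wi(c(0L, 1L), 2)                              # qform, sform codes
  wf(rep(0, 6))                                 # quatern b,c,d + offsets
  wf(c(voxel_size_mm, 0, 0, 0))                 # srow_x
  wf(c(0, voxel_size_mm, 0, 0))                 # srow_y
  wf(c(0, 0, voxel_size_mm, 0))                 # srow_z
  writeBin(raw(16L), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                        # extension flag
  wf(as.numeric(vol))
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports the subset this package writes: single-file little-endian
#' float32/float64/int16/uint8 data.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return a numeric 3D array with attribute `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L) stop("not a little-endian NIfTI-1 file")
  dims <- ri(40L, 2L, 8L)
  if (dims[1] != 3L) stop("only 3D volumes supported")
  shape <- dims[2:4]
  dtype <- ri(70L, 2L)
  pix <- rf(76L, 8L)[2]
  vox_offset <- rf(108L)
  readBin(con, "raw", as.integer(vox_offset) - 348L)
  n <- prod(shape)
  dat <- switch(as.character(dtype),
    "2" = readBin(con, "integer", n, size = 1L, signed = FALSE),
    "4" = readBin(con, "integer", n, size = 2L, endian = "little"),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype ", dtype))
  arr <- array(as.numeric(dat), shape)
  attr(arr, "voxel_size_mm") <- pix
  arr
}
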