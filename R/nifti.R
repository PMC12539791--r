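# Minimal NIfTI-1 reader/writer. Only what this package needs: 3D scalar
# volumes and 3-vector displacement fields, float64 on write, the common
# integer/float datatypes on read, identity-rotation sform, gzip-or-plain
# files. Little-endian on disk; big-endian files are byte-swapped on read.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE),
                 `256` = list(what = "integer", size = 1L, signed = TRUE),
                 `512` = list(what = "integer", size = 2L, signed = FALSE))

nifti_write_raw <- function(arr, spacing, origin, path, intent_code = 0L) {
  dims <- dim(arr)
  nd <- length(dims)
  dimfield <- rep(1L, 8)
  if (nd == 3L) {
    dimfield[1:4] <- c(3L, dims)
  } else if (nd == 4L) {          # vector-valued: store in dim[5]
    dimfield[1:6] <- c(5L, dims[1:3], 1L, dims[4])
  } else stop("only 3D or 4D (vector) arrays supported")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36), con)                         # data_type..dim_info
  wb(as.integer(dimfield), 2L)                   # dim[8]
  wb(numeric(3), 4L)                             # intent_p1..p3
  wb(as.integer(intent_code), 2L)                # intent_code
  wb(64L, 2L)                                    # datatype = float64
  wb(64L, 2L)                                    # bitpix
  wb(0L, 2L)                                     # slice_start
  pixdim <- c(1, spacing, rep(1, 4))
  wb(as.numeric(pixdim), 4L)                     # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  wb(0L, 2L); writeBin(raw(2), con)              # slice_end, slice_code+units
  wb(numeric(4), 4L)                             # cal_max..toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(104), con)                        # descrip + aux_file
  wb(c(0L, 1L), 2L)                              # qform_code=0, sform_code=1
  wb(numeric(6), 4L)                             # quatern b,c,d + qoffset
  wb(c(spacing[1], 0, 0, origin[1]), 4L)         # srow_x
  wb(c(0, spacing[2], 0, origin[2]), 4L)         # srow_y
  wb(c(0, 0, spacing[3], origin[3]), 4L)         # srow_z
  writeBin(raw(16), con)                         # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(5), con)                          # magic pad + 4 bytes to 352
  wb(as.numeric(arr), 8L)
  invisible(path)
}

nifti_read_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  szh <- readBin(con, "integer", 1, 4, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    if (bitwAnd(bitwShiftR(szh, 24), 255L) != 92L && szh != 348L) {
      # re-check: 348 byteswapped is 0x5C010000
    }
  }
  rb <- function(n, what, size, signed = TRUE)
    readBin(con, what, n, size, signed = signed, endian = endian)
  invisible(readBin(con, "raw", 36))
  dimf <- rb(8, "integer", 2)
  if (endian == "little" && (dimf[1] < 1 || dimf[1] > 7)) stop("not a NIfTI-1 file")
  invisible(rb(3, "double", 4)); invisible(rb(1, "integer", 2))
  datatype <- rb(1, "integer", 2)
  invisible(rb(1, "integer", 2)); invisible(rb(1, "integer", 2))
  pixdim <- rb(8, "double", 4)
  vox_offset <- rb(1, "double", 4)
  scl_slope <- rb(1, "double", 4)
  scl_inter <- rb(1, "double", 4)
  invisible(rb(1, "integer", 2)); invisible(readBin(con, "raw", 2))
  invisible(rb(4, "double", 4)); invisible(rb(2, "integer", 4))
  invisible(readBin(con, "raw", 104))
  invisible(rb(2, "integer", 2))                 # qform, sform codes
  invisible(rb(6, "double", 4))
  srow <- matrix(rb(12, "double", 4), 3, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 16))
  magic <- rawToChar(readBin(con, "raw", 4)[1:3])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
  nd <- dimf[1]
  if (!(nd %in% c(3L, 4L, 5L))) stop("only 3D volumes / vector fields supported")
  dims3 <- dimf[2:4]
  ncomp <- if (nd == 5L) max(1L, dimf[6]) else if (nd == 4L) max(1L, dimf[5]) else 1L
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", skip))
  n <- prod(dims3) * ncomp
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spacing <- pixdim[2:4]
  origin <- srow[, 4]
  list(values = vals, dims = dims3, ncomp = ncomp,
       spacing = spacing, origin = origin)
}

#' Read a NIfTI-1 volume
#'
#' Reads a scalar 3D NIfTI-1/-2-style `.nii` or `.nii.gz` file (NIfTI-1
#' layout) into an [image_volume()] or, with `mask = TRUE`, a
#' [mask_volume()].
#'
#' @param path file path.
#' @param mask coerce to a binary mask (values must already be 0/1).
#' @return an `image_volume` or `mask_volume`.
#' @export
read_volume <- function(path, mask = FALSE) {
  r <- nifti_read_raw(path)
  if (r$ncomp != 1L) stop("expected a scalar volume; use read_field() for fields")
  arr <- array(r$values, r$dims)
  if (mask) mask_volume(arr, r$spacing, r$origin)
  else image_volume(arr, r$spacing, r$origin)
}

#' Write a volume as NIfTI-1
#'
#' Voxels are stored as float64 so values, spacing and origin round-trip
#' losslessly. A `.gz` suffix triggers gzip compression.
#'
#' @param vol an [image_volume()] or [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  nifti_write_raw(vol$voxels, vol$spacing, vol$origin, path)
}

#' Read a displacement field from 3-channel NIfTI
#'
#' @param path file path written by [write_field()] (or any NIfTI-1 file
#'   with three components in dim 4/5; displacements in voxel units,
#'   channel order x,y,z of the index frame).
#' @return a [displacement_field()].
#' @export
read_field <- function(path) {
  r <- nifti_read_raw(path)
  if (r$ncomp != 3L) stop("expected a 3-component displacement field")
  u <- array(r$values, c(r$dims, 3L))
  displacement_field(u, cube_grid(r$dims[1], r$spacing[1]))
}

#' Write a displacement field as 3-channel NIfTI
#' @param field a [displacement_field()].
#' @param path output path.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  s <- rep(field$grid$voxel_size, 3)
  nifti_write_raw(field$u, s, c(0, 0, 0), path, intent_code = 1006L)
}
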