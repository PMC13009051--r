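# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI reader is available in the package's dependency set, so the subset
# of the format needed for binary segmentation masks is implemented here:
# 3D volumes, datatypes uint8/int16/int32/float32/float64/uint16, little- or
# big-endian (detected from sizeof_hdr), axis-aligned sform/qform offsets.
# Rotational sform/qform components are ignored with a warning; spacing is
# always taken from pixdim, as is standard for shape radiomics.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Low-level reader returning the raw voxel array plus geometry. Most users
#' want [load_mask()], which also binarizes and validates.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3D numeric array), `spacing`
#'   (length-3, mm/voxel) and `origin` (length-3, mm; physical position of the
#'   center of voxel (0,0,0)).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .nifti_con(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int4(sizeof_hdr) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  readBin(con, "raw", 36)                                     # unused header fields
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "raw", 14)                                     # intent_p1..3, intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "raw", 4)                                      # bitpix, slice_start
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  readBin(con, "raw", 132)                                    # up to qform_code
  qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  quat <- readBin(con, "double", 6, size = 4, endian = endian) # quatern_b..d, qoffset_x..z
  srow <- matrix(readBin(con, "double", 12, size = 4, endian = endian), 3, 4, byrow = TRUE)
  readBin(con, "raw", 16)                                     # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (startsWith(magic, "ni1"))
    stop("two-file (.hdr/.img) NIfTI is not supported: ", path)

  nd <- dim8[1]
  if (nd < 3L) stop("volume is not 3D (dim[0] = ", nd, "): ", path)
  dims <- dim8[2:(nd + 1)]
  if (nd > 3L) {
    if (prod(dims[4:nd]) != 1L) stop("volume is not 3D (non-singleton dim > 3): ", path)
    dims <- dims[1:3]
  }
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive voxel spacing in header: ", paste(signif(spacing, 4), collapse = "x"))

  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)

  # header ends at byte 348; skip forward to vox_offset (seek is unreliable
  # on gzfile connections, so consume bytes instead)
  if (vox_offset > 348) readBin(con, "raw", vox_offset - 348)
  n <- prod(dims)
  data <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed, endian = endian)
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  data <- array(as.double(data), dim = dims)

  origin <- c(0, 0, 0)
  if (sform_code > 0) {
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(spacing)))
      warning("non-axis-aligned sform ignored; using pixdim spacing and sform offset only")
    origin <- srow[, 4]
  } else if (qform_code > 0) {
    origin <- quat[4:6]
  }
  list(data = data, spacing = spacing, origin = origin)
}

.swap_int4 <- function(x) {
  r <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
  readBin(rev(r), "integer", 1, size = 4, endian = "little")
}

#' Write a 3D array as NIfTI-1
#'
#' Writes a single-file NIfTI-1 volume (uint8 for binary data, float64
#' otherwise), little-endian, with an axis-aligned sform carrying the spacing
#' and origin.
#'
#' @param data 3D numeric array.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param spacing Voxel spacing in mm (length 3).
#' @param origin Physical position (mm) of the center of voxel (0,0,0).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  binary <- all(data %in% c(0, 1))
  datatype <- if (binary) 2L else 64L
  bitpix <- if (binary) 8L else 64L

  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f4 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348)                              # sizeof_hdr
  w_raw(36)                              # data_type..dim_info
  w_i2(c(3L, dim(data), 1L, 1L, 1L, 1L)) # dim
  w_raw(12)                              # intent_p1..3
  w_i2(0)                                # intent_code
  w_i2(datatype); w_i2(bitpix); w_i2(0)  # datatype, bitpix, slice_start
  w_f4(c(1, spacing, 1, 1, 1, 1))        # pixdim
  w_f4(352)                              # vox_offset
  w_f4(1); w_f4(0)                       # scl_slope, scl_inter
  w_i2(0); w_raw(2)                      # slice_end, slice_code, xyzt_units
  w_f4(c(0, 0, 0, 0))                    # cal_max..toffset
  w_i4(c(0, 0))                          # glmax, glmin
  w_raw(104)                             # descrip, aux_file
  w_i2(0); w_i2(1)                       # qform_code, sform_code
  w_f4(rep(0, 6))                        # quatern_b..d, qoffset
  w_f4(c(spacing[1], 0, 0, origin[1]))   # srow_x
  w_f4(c(0, spacing[2], 0, origin[2]))   # srow_y
  w_f4(c(0, 0, spacing[3], origin[3]))   # srow_z
  w_raw(16)                              # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1)  # magic
  w_raw(4)                               # extension flag
  if (binary) {
    writeBin(as.integer(data), con, size = 1)
  } else {
    writeBin(as.double(data), con, size = 8, endian = "little")
  }
  invisible(path)
}
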