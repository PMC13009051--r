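# SegmentationMask: binary 3D voxel grid + physical geometry.
# Convention: the center of voxel (i, j, k) (0-based) sits at
# origin + c(i, j, k) * spacing, all in mm.

#' Construct a segmentation mask
#'
#' @param voxels 3D array; any nonzero entry is foreground and is stored as
#'   integer 1. Non-binary (fractional) arrays are rejected — probability or
#'   partial-volume maps must be thresholded explicitly by the caller.
#' @param spacing Voxel spacing in mm (length 3, all > 0).
#' @param origin Physical position (mm) of the center of voxel (0,0,0).
#' @return An object of class `seg_mask` with fields `voxels`, `spacing`,
#'   `origin`.
#' @export
segmentation_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  v <- as.double(voxels)
  if (any(is.na(v))) stop("voxels contain NA")
  if (any(v != round(v)))
    stop("voxels are not label-valued; refusing to threshold a probability/partial-volume map")
  vox <- array(as.integer(v != 0), dim = dim(voxels))
  if (sum(vox) == 0L) stop("empty mask: no foreground voxel")
  structure(list(voxels = vox, spacing = spacing, origin = origin),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("<seg_mask> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, ", sum(x$voxels), " foreground (",
      signif(mask_volume(x), 6), " mm^3)\n", sep = "")
  invisible(x)
}

#' Foreground volume by voxel counting
#'
#' Foreground voxel count times the voxel volume — the simple volume
#' estimator, used as an independent cross-check of the mesh-based volume.
#'
#' @param mask A `seg_mask`.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  sum(mask$voxels) * prod(mask$spacing)
}

#' Load a binary segmentation mask from NIfTI
#'
#' Reads a labeled or binary NIfTI volume and extracts one label as a binary
#' mask, with spacing and origin taken from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` volume.
#' @param label Positive integer label to extract, or `NULL` (default) to
#'   treat any nonzero voxel as foreground.
#' @return A [segmentation_mask()].
#' @export
load_mask <- function(path, label = NULL) {
  nii <- read_nifti(path)
  d <- nii$data
  if (any(d != round(d)))
    stop("volume is not label-valued; refusing to threshold a probability map: ", path)
  if (!is.null(label)) {
    label <- as.double(label)
    if (length(label) != 1L || label <= 0 || label != round(label))
      stop("label must be a single positive integer")
    d <- (d == label) * 1
    if (sum(d) == 0) stop("empty mask: no voxel matches label ", label, " in ", path)
  } else if (sum(d != 0) == 0) {
    stop("empty mask: no nonzero voxel in ", path)
  }
  segmentation_mask(d, spacing = nii$spacing, origin = nii$origin)
}

#' Write a segmentation mask to NIfTI
#'
#' @param mask A `seg_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  write_nifti(mask$voxels, path, spacing = mask$spacing, origin = mask$origin)
}

#' Resample a mask to isotropic spacing
#'
#' Nearest-neighbor resampling onto an isotropic grid covering the same
#' physical extent; keeps the mask strictly binary. Resampling at the mask's
#' own (isotropic) spacing is the identity.
#'
#' @param mask A `seg_mask`.
#' @param target Target spacing in mm (> 0), applied to all three axes.
#' @return A `seg_mask` with spacing `c(target, target, target)`.
#' @export
resample_isotropic <- function(mask, target) {
  stopifnot(inherits(mask, "seg_mask"))
  target <- as.double(target)
  if (length(target) != 1L || !is.finite(target) || target <= 0)
    stop("target spacing must be a single positive value (mm)")
  dm <- dim(mask$voxels); sp <- mask$spacing
  if (all(abs(sp - target) < 1e-12)) return(mask)
  ndim <- pmax(1L, as.integer(floor((dm - 1L) * sp / target + 1e-9)) + 1L)
  # nearest old voxel center for each new center (0-based indices)
  maps <- lapply(1:3, function(a) {
    idx <- as.integer(round((seq_len(ndim[a]) - 1L) * target / sp[a]))
    pmin(pmax(idx, 0L), dm[a] - 1L) + 1L
  })
  vox <- mask$voxels[maps[[1]], maps[[2]], maps[[3]], drop = FALSE]
  dim(vox) <- ndim
  if (sum(vox) == 0L) stop("resampling at ", target, " mm emptied the mask")
  segmentation_mask(vox, spacing = rep(target, 3), origin = mask$origin)
}

#' Keep only the largest connected component
#'
#' Retains the largest 26-connected foreground component. Exact ties in size
#' are broken deterministically toward the component containing the smallest
#' linear (column-major) voxel index.
#'
#' @param mask A `seg_mask`.
#' @return A `seg_mask` whose foreground is a subset of the input foreground.
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  lab <- cpp_label_components(mask$voxels, dim(mask$voxels))
  sizes <- tabulate(lab[lab > 0L])
  # labels are assigned in scan order, so among equal sizes the smallest
  # label is the component seen first (lowest linear seed index)
  keep <- which(sizes == max(sizes))[1]
  vox <- array(as.integer(lab == keep), dim = dim(mask$voxels))
  segmentation_mask(vox, spacing = mask$spacing, origin = mask$origin)
}
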