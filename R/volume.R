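#' Construct a 3D scalar volume
#'
#' A `seg_volume` is the image a segmenter consumes: a 3D scalar grid with
#' per-axis voxel spacing in millimetres. The package uses a fixed axis
#' convention: axis 1 runs sagittally left-to-right, axis 2
#' anterior-to-posterior, axis 3 inferior-to-superior. "Lateral" therefore
#' always means along axis 1, with positive sign pointing away from the
#' mid-sagittal plane for a right-sided structure.
#'
#' @param voxels 3D numeric array of intensities (CT-like, arbitrary units).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @return object of class `seg_volume`.
#' @export
seg_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("non-3D image: `voxels` must be a 3D array")
  if (any(dim(voxels) == 0L)) stop("empty grid")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("non-positive spacing")
  structure(list(voxels = voxels, spacing = spacing), class = "seg_volume")
}

#' Construct a binary mask aligned to a volume grid
#'
#' @param voxels 3D array with values in \{0, 1\}.
#' @param spacing numeric length-3 voxel size in mm (same grid as the paired
#'   volume).
#' @return object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("non-3D image: `voxels` must be a 3D array")
  u <- unique(as.vector(voxels))
  if (!all(u %in% c(0, 1))) stop("mask is not binary: values outside {0,1}")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("non-positive spacing")
  v <- array(as.integer(voxels), dim = dim(voxels))
  structure(list(voxels = v, spacing = spacing), class = "seg_mask")
}

#' @export
print.seg_volume <- function(x, ...) {
  cat(sprintf("<seg_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.seg_volume <- function(x) dim(x$voxels)

#' @export
dim.seg_mask <- function(x) dim(x$voxels)

mask_volume_voxels <- function(mask) sum(mask$voxels)

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

#' Read a NIfTI volume
#'
#' Spacing is taken from the file's `pixdim` header. The on-disk axis order
#' is taken to already follow the package convention (see [seg_volume()]),
#' so loading a file the package wrote changes nothing.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [seg_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L) stop("non-3D image: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(sp <= 0)) stop("non-positive spacing in header: ", path)
  seg_volume(array(as.numeric(img), dim = d), spacing = sp)
}

#' Read a NIfTI file as a binary mask
#'
#' Voxels are thresholded at `> 0` so masks written by foreign tools with
#' other positive label values load as foreground.
#'
#' @inheritParams read_volume
#' @return a [seg_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  seg_mask(array(as.integer(v$voxels > 0), dim = dim(v$voxels)),
           spacing = v$spacing)
}

#' Write a volume to NIfTI
#'
#' @param volume a [seg_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "seg_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask to NIfTI (unsigned 8-bit)
#'
#' @param mask a [seg_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
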