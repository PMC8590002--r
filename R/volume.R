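#' Voxel volume and ROI mask containers
#'
#' A `voxel_volume` is a 3D scalar grid in HU-like units plus its physical
#' voxel spacing; a `roi_mask` is a congruent binary tumor mask. Arrays are
#' stored column-major with axes `(x, y, z)` where `z` indexes axial slices,
#' matching the convention of [RNifti::readNifti()].
#'
#' @param values 3D numeric array (volume) or logical/0-1 array (mask).
#' @param spacing_mm Positive numeric length 3, voxel size per axis in mm.
#' @return An object of class `voxel_volume` or `roi_mask`.
#' @export
voxel_volume <- function(values, spacing_mm = c(1, 1, 1)) {
  values <- unclass(values)
  if (length(dim(values)) != 3) stop_radguide("volume must be a 3D array")
  if (!all(is.finite(values))) stop_radguide("volume has non-finite voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop_radguide("spacing_mm must be 3 positive values")
  }
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "voxel_volume")
}

#' @rdname voxel_volume
#' @export
roi_mask <- function(values, spacing_mm = c(1, 1, 1)) {
  values <- unclass(values)
  if (length(dim(values)) != 3) stop_radguide("mask must be a 3D array")
  v <- array(values != 0, dim = dim(values))
  if (!any(v)) stop_radguide("mask has no foreground voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop_radguide("spacing_mm must be 3 positive values")
  }
  structure(list(values = v, spacing_mm = spacing_mm), class = "roi_mask")
}

#' @exportS3Method base::print
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume>", paste(dim(x$values), collapse = "x"),
      "voxels, spacing", paste(x$spacing_mm, collapse = "x"), "mm\n")
  invisible(x)
}

#' @exportS3Method base::print
print.roi_mask <- function(x, ...) {
  cat("<roi_mask>", paste(dim(x$values), collapse = "x"), "voxels,",
      sum(x$values), "foreground\n")
  invisible(x)
}

check_congruent <- function(volume, mask) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$values), dim(mask$values))) {
    stop_radguide("volume and mask grids differ: ",
                  paste(dim(volume$values), collapse = "x"), " vs ",
                  paste(dim(mask$values), collapse = "x"))
  }
  invisible(TRUE)
}

#' Read and write volumes/masks as NIfTI
#'
#' Thin wrappers over the RNifti reader/writer that carry the voxel
#' spacing. Masks are binarized (`!= 0`) on read.
#'
#' @param x A [voxel_volume()] or [roi_mask()].
#' @param path File path, conventionally ending in `.nii.gz`.
#' @return `read_volume`/`read_mask` return the corresponding container.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("voxel_volume", "roi_mask")))
  img <- RNifti::asNifti(array(as.numeric(x$values), dim = dim(x$values)))
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) != 0, dim = dim(img)[1:3]),
           RNifti::pixdim(img)[1:3])
}

# mm coordinates of voxel centers along one axis (0-based index * spacing)
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing
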