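#' Image volume and segmentation mask containers
#'
#' An `image_volume` holds a 3-D grid of CT intensities in Hounsfield units
#' (HU) together with its voxel spacing in mm and origin. A
#' `segmentation_mask` holds an aligned 3-D binary grid (1 = nodule,
#' 0 = background). Both are plain lists so that downstream numeric code can
#' work on the raw arrays.
#'
#' @param voxels 3-D numeric array (HU for images, 0/1 for masks).
#' @param spacing_mm Positive length-3 numeric vector of voxel spacing in mm.
#' @param origin_mm Length-3 numeric vector, physical position of the first
#'   voxel centre (default 0).
#' @return An object of class `image_volume` or `segmentation_mask` with
#'   elements `voxels`, `spacing_mm` and `origin_mm`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 2))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  check_grid(voxels, spacing_mm)
  structure(list(voxels = voxels,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
segmentation_mask <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  check_grid(voxels, spacing_mm)
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "segmentation_mask")
}

check_grid <- function(voxels, spacing_mm) {
  if (length(dim(voxels)) != 3L) stopf("not a 3D volume")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stopf("spacing_mm must be 3 positive finite numbers")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              sum(x$voxels)))
  invisible(x)
}

# Image/mask pair validation: same grid, spacing agreement within tol mm
# (real-world exports carry float jitter in the affine).
check_pair <- function(volume, mask, tol = 1e-3) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stopf("image/mask grid mismatch: image %s vs mask %s",
          paste(dim(volume$voxels), collapse = "x"),
          paste(dim(mask$voxels), collapse = "x"))
  if (any(abs(volume$spacing_mm - mask$spacing_mm) > tol))
    stopf("image/mask spacing mismatch beyond %g mm tolerance", tol)
  invisible(TRUE)
}

#' Read and write volumes in NIfTI format
#'
#' `read_volume()` loads a `.nii`/`.nii.gz` file, reorients it to the
#' canonical RAS axes when a full affine is present (so the third array axis
#' is the axial direction), and returns either an [image_volume()] or, with
#' `as_mask = TRUE`, a [segmentation_mask()] binarised as value > 0.
#' `write_volume()` performs the inverse.
#'
#' @param path File path.
#' @param as_mask Logical; binarise to a segmentation mask.
#' @return `read_volume()`: an `image_volume` or `segmentation_mask`;
#'   `write_volume()`: the path, invisibly.
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("unreadable NIfTI file %s: %s",
                                            path, conditionMessage(e)))
  img <- tryCatch(suppressWarnings({ RNifti::orientation(img) <- "RAS"; img }),
                  error = function(e) img)
  if (length(dim(img)) != 3L) {
    if (length(dim(img)) > 3L && all(dim(img)[-(1:3)] == 1L)) {
      img <- array(as.numeric(img), dim = dim(img)[1:3])
    } else {
      stopf("not a 3D volume: %s has dimensions %s", path,
            paste(dim(img), collapse = "x"))
    }
  }
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- abs(as.numeric(sp)[1:3])
  vox <- array(as.numeric(img), dim = dim(img)[1:3])
  if (as_mask) segmentation_mask(vox > 0, sp) else image_volume(vox, sp)
}

#' @rdname read_volume
#' @param x An `image_volume` or `segmentation_mask`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "segmentation_mask"))
  img <- RNifti::asNifti(x$voxels)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
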