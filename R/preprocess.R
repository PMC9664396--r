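#' Resample a volume or mask to a target voxel spacing
#'
#' Images are interpolated with separable natural cubic splines along each
#' axis; masks with nearest-neighbour lookup, so mask outputs stay binary.
#' The output grid covers the same physical extent: the voxel count along
#' each axis is `round(n * spacing_in / spacing_out)` (at least 1), and
#' voxel centres of both grids are aligned to a shared physical origin at
#' the corner of the field of view.
#'
#' @param x An [image_volume()] or [segmentation_mask()].
#' @param target_spacing_mm Positive length-3 spacing in mm, e.g.
#'   `c(1, 1, 2)`.
#' @param mode `"image"` (cubic spline) or `"mask"` (nearest neighbour);
#'   defaults to the type of `x`.
#' @return Object of the same class as `x` at the target spacing.
#' @examples
#' ph <- generate_phantom(phantom_spec(spacing_mm = c(0.7, 0.7, 1.5)))
#' rs <- resample(ph$mask, c(1, 1, 2))
#' rs$spacing_mm
#' @export
resample <- function(x, target_spacing_mm,
                     mode = if (inherits(x, "segmentation_mask")) "mask"
                            else "image") {
  stopifnot(inherits(x, "image_volume") || inherits(x, "segmentation_mask"))
  mode <- match.arg(mode, c("image", "mask"))
  if (length(target_spacing_mm) != 3L || any(target_spacing_mm <= 0))
    stopf("target spacing must be 3 positive numbers")
  sp_in <- x$spacing_mm
  sp_out <- as.numeric(target_spacing_mm)
  n_in <- dim(x$voxels)
  n_out <- pmax(1L, as.integer(round(n_in * sp_in / sp_out)))
  # continuous input index of each output voxel centre, per axis
  qidx <- lapply(1:3, function(ax)
    ((seq_len(n_out[ax]) - 0.5) * sp_out[ax]) / sp_in[ax] + 0.5)
  if (mode == "mask") {
    nn <- lapply(1:3, function(ax)
      pmin(pmax(round(qidx[[ax]]), 1L), n_in[ax]))
    out <- x$voxels[nn[[1]], nn[[2]], nn[[3]], drop = FALSE]
    segmentation_mask(out, sp_out, x$origin_mm)
  } else {
    a <- x$voxels
    for (ax in 1:3) a <- spline_interp_axis(a, qidx[[ax]], ax)
    image_volume(a, sp_out, x$origin_mm)
  }
}

# Natural cubic-spline interpolation of a 3-D array along one axis at
# (possibly out-of-range, clamped) continuous indices `q`.
spline_interp_axis <- function(a, q, axis) {
  d <- dim(a)
  n <- d[axis]
  q <- pmin(pmax(q, 1), n)
  perm <- switch(axis, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
  b <- aperm(a, perm)
  db <- dim(b)
  m <- matrix(b, nrow = db[1L])
  if (n == 1L) {
    out <- m[rep(1L, length(q)), , drop = FALSE]
  } else {
    xs <- seq_len(n)
    out <- apply(m, 2L, function(v)
      stats::splinefun(xs, v, method = "natural")(q))
    out <- matrix(out, nrow = length(q))
  }
  dim(out) <- c(length(q), db[2L], db[3L])
  aperm(out, order(perm))
}

#' Cap intensities to a fixed HU range
#'
#' Clamps every voxel to `[lo, hi]`; values already inside the range are
#' unchanged, so capping is idempotent. Applied after resampling so that
#' cubic-spline overshoot is also clamped.
#'
#' @param volume An [image_volume()].
#' @param lo,hi Range bounds in HU (default -2000 to +2000).
#' @return An `image_volume` with all intensities in `[lo, hi]`.
#' @export
cap_intensities <- function(volume, lo = -2000, hi = 2000) {
  stopifnot(inherits(volume, "image_volume"))
  if (lo >= hi) stopf("lower cap (%g) must be below upper cap (%g)", lo, hi)
  volume$voxels <- pmin(pmax(volume$voxels, lo), hi)
  volume
}

#' Crop an image/mask pair to the mask bounding box
#'
#' The output grid is the tight bounding box of the mask foreground,
#' dilated by `margin_voxels` on every side and clipped to the original
#' grid. All foreground voxels are retained.
#'
#' @param volume An [image_volume()].
#' @param mask The paired [segmentation_mask()].
#' @param margin_voxels Non-negative integer margin.
#' @return List with cropped `image` and `mask`.
#' @export
crop_to_mask <- function(volume, mask, margin_voxels = 0L) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(mask, "segmentation_mask"), margin_voxels >= 0)
  check_pair(volume, mask)
  if (sum(mask$voxels) == 0L) stopf("cannot crop to an empty mask")
  idx <- which(mask$voxels != 0L, arr.ind = TRUE)
  m <- as.integer(margin_voxels)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, min(idx[, ax]) - m)
    hi <- min(dim(mask$voxels)[ax], max(idx[, ax]) + m)
    lo:hi
  })
  list(image = image_volume(volume$voxels[rng[[1]], rng[[2]], rng[[3]],
                                          drop = FALSE],
                            volume$spacing_mm, volume$origin_mm),
       mask = segmentation_mask(mask$voxels[rng[[1]], rng[[2]], rng[[3]],
                                            drop = FALSE],
                                mask$spacing_mm, mask$origin_mm))
}

#' Standard preprocessing for feature extraction
#'
#' Resamples the pair to `spacing` (cubic spline for the image, nearest
#' neighbour for the mask), caps image intensities to `[cap[1], cap[2]]`,
#' and crops both to the mask bounding box with `margin_voxels`.
#'
#' @inheritParams crop_to_mask
#' @param spacing Target spacing (default 1 x 1 x 2 mm).
#' @param cap Length-2 HU capping range.
#' @return List with preprocessed `image` and `mask`.
#' @export
preprocess_pair <- function(volume, mask, spacing = c(1, 1, 2),
                            cap = c(-2000, 2000), margin_voxels = 0L) {
  check_pair(volume, mask)
  img <- resample(volume, spacing, mode = "image")
  msk <- resample(mask, spacing, mode = "mask")
  img <- cap_intensities(img, cap[1], cap[2])
  crop_to_mask(img, msk, margin_voxels)
}
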