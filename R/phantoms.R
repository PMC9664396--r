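#' Specify a synthetic nodule phantom
#'
#' A phantom is a nodule-shaped region (sphere, or sphere plus radial
#' conical spikes emulating spiculation) filled at `nodule_hu` inside a
#' uniform `background_hu` field, optionally overlaid with Gaussian noise
#' whose spatial autocorrelation is controlled by
#' `texture_correlation_length_mm`. Shapes have analytically known volume,
#' surface area and diameter, which makes every downstream stage of the
#' pipeline testable without patient scans.
#'
#' @param shape_kind `"sphere"` or `"spiculated"`.
#' @param radius_mm Sphere radius (mm), positive.
#' @param n_spikes Number of conical spikes for spiculated shapes (placed at
#'   quasi-uniform Fibonacci-sphere directions).
#' @param spike_length_mm Spike length beyond the sphere surface (mm).
#' @param spike_base_mm Spike base radius at the sphere surface (mm).
#' @param nodule_hu,background_hu Fill intensities (HU). Defaults emulate a
#'   soft-tissue nodule in aerated lung.
#' @param noise_sd_hu Standard deviation of additive Gaussian noise (HU).
#' @param texture_correlation_length_mm Isotropic Gaussian correlation
#'   length of the noise field; 0 gives white noise.
#' @param spacing_mm Voxel spacing, length 3 (mm).
#' @param grid_shape Voxel counts, length 3; `NULL` sizes the grid to fit
#'   the shape with a 4 mm margin.
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @return A `phantom_spec` list.
#' @examples
#' spec <- phantom_spec(radius_mm = 10, spacing_mm = c(1, 1, 1))
#' ph <- generate_phantom(spec)
#' sum(ph$mask$voxels) * prod(spec$spacing_mm)  # ~ (4/3) pi 10^3
#' @export
phantom_spec <- function(shape_kind = c("sphere", "spiculated"),
                         radius_mm = 10,
                         n_spikes = 12L,
                         spike_length_mm = 6,
                         spike_base_mm = radius_mm / 3,
                         nodule_hu = 40,
                         background_hu = -800,
                         noise_sd_hu = 0,
                         texture_correlation_length_mm = 0,
                         spacing_mm = c(1, 1, 2),
                         grid_shape = NULL,
                         seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  stopifnot(is_scalar_number(radius_mm), radius_mm > 0,
            is_scalar_number(spike_length_mm), spike_length_mm >= 0,
            is_scalar_number(noise_sd_hu), noise_sd_hu >= 0,
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (texture_correlation_length_mm < 0)
    stopf("texture_correlation_length_mm must be non-negative")
  n_spikes <- as.integer(n_spikes)
  if (n_spikes < 0) stopf("n_spikes must be non-negative")
  extent <- radius_mm + if (shape_kind == "spiculated") spike_length_mm else 0
  if (is.null(grid_shape))
    grid_shape <- as.integer(ceiling((2 * extent + 8) / spacing_mm))
  grid_shape <- as.integer(grid_shape)
  # require the shape to fit with a >= 2-voxel margin on every axis
  half_mm <- grid_shape * spacing_mm / 2
  for (ax in 1:3) {
    if (extent > half_mm[ax] - 2 * spacing_mm[ax])
      stopf("shape of extent %.1f mm exceeds grid on axis %d (%d voxels x %g mm)",
            extent, ax, grid_shape[ax], spacing_mm[ax])
  }
  structure(list(shape_kind = shape_kind, radius_mm = radius_mm,
                 n_spikes = n_spikes, spike_length_mm = spike_length_mm,
                 spike_base_mm = spike_base_mm,
                 nodule_hu = nodule_hu, background_hu = background_hu,
                 noise_sd_hu = noise_sd_hu,
                 texture_correlation_length_mm = texture_correlation_length_mm,
                 spacing_mm = as.numeric(spacing_mm),
                 grid_shape = grid_shape, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Quasi-uniform unit directions via the Fibonacci sphere.
fibonacci_directions <- function(n) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Voxel-centre coordinates relative to the grid centre, as an N x 3 matrix.
voxel_coords <- function(grid_shape, spacing_mm) {
  ax <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - 0.5) - grid_shape[a] / 2) * spacing_mm[a])
  cbind(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]),
        rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]),
        rep(ax[[3]], each = grid_shape[1] * grid_shape[2]))
}

voxelise_shape <- function(spec) {
  xyz <- voxel_coords(spec$grid_shape, spec$spacing_mm)
  d2 <- rowSums(xyz^2)
  inside <- d2 <= spec$radius_mm^2
  if (spec$shape_kind == "spiculated" && spec$n_spikes > 0L &&
      spec$spike_length_mm > 0) {
    dirs <- fibonacci_directions(spec$n_spikes)
    r0 <- spec$radius_mm
    L <- spec$spike_length_mm
    w0 <- spec$spike_base_mm
    proj <- xyz %*% t(dirs)                     # N x K axial coordinates
    for (k in seq_len(spec$n_spikes)) {
      t_ax <- proj[, k]
      cand <- t_ax > 0 & t_ax <= r0 + L & !inside
      if (!any(cand)) next
      perp2 <- d2[cand] - t_ax[cand]^2
      # cone: full width w0 at the sphere surface, tapering to 0 at the tip
      wt <- w0 * pmax(0, 1 - (t_ax[cand] - r0) / L)
      inside[cand] <- inside[cand] | (perp2 <= wt^2 & t_ax[cand] >= r0 - w0)
    }
  }
  array(as.integer(inside), dim = spec$grid_shape)
}

#' Generate a phantom image/mask pair
#'
#' `generate_phantom()` voxelises the shape exactly (a voxel is foreground
#' iff its centre lies inside the analytic shape) and composes the image as
#' background + nodule fill + optional Gaussian noise.
#' `generate_textured_phantom()` is the texture-focused variant: the noise
#' field is smoothed with an isotropic Gaussian kernel of
#' `texture_correlation_length_mm` *before* masking, so boundary voxels
#' share the field's autocorrelation, and is rescaled to `noise_sd_hu`
#' after smoothing. A correlation length of 0 gives white noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([image_volume()]) and `mask`
#'   ([segmentation_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- voxelise_shape(spec)
  img <- array(spec$background_hu, dim = spec$grid_shape)
  img[mask == 1L] <- spec$nodule_hu
  if (spec$noise_sd_hu > 0) {
    noise <- with_seed(spec$seed, array(stats::rnorm(prod(spec$grid_shape)),
                                        dim = spec$grid_shape))
    if (spec$texture_correlation_length_mm > 0) {
      sig_vox <- spec$texture_correlation_length_mm / spec$spacing_mm
      noise <- gaussian_smooth3d(noise, sig_vox)
      noise <- noise / stats::sd(noise)
    }
    img <- img + spec$noise_sd_hu * noise
  }
  list(image = image_volume(img, spec$spacing_mm),
       mask = segmentation_mask(mask, spec$spacing_mm))
}

#' @rdname generate_phantom
#' @export
generate_textured_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$texture_correlation_length_mm < 0)
    stopf("texture_correlation_length_mm must be non-negative")
  generate_phantom(spec)
}

#' Write a phantom pair as NIfTI files
#'
#' @param phantom List from [generate_phantom()].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Named character vector with the image and mask paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(prefix, "_image.nii.gz")),
             mask = file.path(dir, paste0(prefix, "_mask.nii.gz")))
  write_volume(phantom$image, paths[["image"]])
  write_volume(phantom$mask, paths[["mask"]])
  paths
}
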