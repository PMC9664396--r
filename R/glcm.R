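#' Quantise in-mask intensities into fixed-width HU bins
#'
#' Grey levels are assigned as `floor((I - anchor) / bin_width) + 1` with
#' the anchor at the in-mask minimum, the standard fixed-bin-width
#' convention: level 1 starts at the minimum and adding a constant to every
#' voxel leaves the level array unchanged. A flat region maps to a single
#' level (K = 1).
#'
#' @param volume An [image_volume()] (intensities already capped).
#' @param mask Paired [segmentation_mask()], non-empty.
#' @param bin_width Bin width in HU (default 25).
#' @return A `quantised_roi`: list with `levels` (3-D integer array, 0
#'   outside the mask, 1..K inside), `K`, `bin_width`, `bin_anchor`.
#' @export
quantise <- function(volume, mask, bin_width = 25) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(mask, "segmentation_mask"), bin_width > 0)
  check_pair(volume, mask)
  inmask <- mask$voxels != 0L
  if (!any(inmask)) stopf("cannot quantise an empty mask")
  vals <- volume$voxels[inmask]
  anchor <- min(vals)
  lev <- array(0L, dim = dim(volume$voxels))
  lev[inmask] <- as.integer(floor((volume$voxels[inmask] - anchor) /
                                    bin_width)) + 1L
  K <- max(lev)
  structure(list(levels = lev, K = K, bin_width = bin_width,
                 bin_anchor = anchor, spacing_mm = volume$spacing_mm),
            class = "quantised_roi")
}

#' The 13 unique 3-D co-occurrence offsets
#'
#' All direction vectors with components in \{-1, 0, 1\} at Chebyshev
#' distance 1, keeping one of each +/- pair (first non-zero component
#' positive). Offsets are taken in voxel steps on the working grid.
#'
#' @return 13 x 3 integer matrix.
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(v) v[which(v != 0)[1]] > 0)
  out <- g[keep, , drop = FALSE]
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Grey-level co-occurrence matrix for one offset
#'
#' Counts ordered level pairs `(i, j)` of voxels both inside the mask and
#' separated by `offset * distance`, symmetrises by adding the transpose,
#' and normalises to probabilities.
#'
#' @param roi A [quantise()]d ROI.
#' @param offset Integer length-3 direction vector (non-zero).
#' @param distance Integer step multiplier (default 1).
#' @return A `glcm`: list with `counts` (symmetrised K x K), `p`
#'   (probabilities summing to 1), `K`, `offset`, and `empty` (TRUE when no
#'   valid pair exists for the offset).
#' @export
glcm_for_offset <- function(roi, offset, distance = 1L) {
  stopifnot(inherits(roi, "quantised_roi"), length(offset) == 3L)
  off <- as.integer(offset) * as.integer(distance)
  if (all(off == 0L)) stopf("offset must be non-zero")
  lev <- roi$levels
  d <- dim(lev)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, 1L - off[ax]); hi <- min(d[ax], d[ax] - off[ax])
    if (lo > hi) integer(0) else lo:hi
  })
  K <- roi$K
  counts <- matrix(0, K, K)
  if (all(lengths(rng) > 0L)) {
    a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3],
             drop = FALSE]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      tab <- tabulate((a[ok] - 1L) * K + b[ok], nbins = K * K)
      counts <- matrix(tab, K, K, byrow = TRUE)
      counts <- counts + t(counts)
    }
  }
  tot <- sum(counts)
  structure(list(counts = counts,
                 p = if (tot > 0) counts / tot else counts,
                 K = K, offset = off, empty = tot == 0),
            class = "glcm")
}

#' GLCM correlation
#'
#' The linear dependency of co-occurring grey levels:
#' `sum_ij p(i,j) (i - mu_i)(j - mu_j) / (sigma_i sigma_j)`, always in
#' \[-1, 1\]. For a degenerate (flat-region) GLCM with zero marginal
#' variance the value is defined as 1, the usual radiomics convention.
#'
#' @param glcm A [glcm_for_offset()] result.
#' @return Correlation in \[-1, 1\], or `NA` for a flagged-empty GLCM.
#' @export
glcm_correlation <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  if (glcm$empty) return(NA_real_)
  p <- glcm$p
  i <- seq_len(glcm$K)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj_)
  var_i <- sum((i - mu_i)^2 * pi_); var_j <- sum((i - mu_j)^2 * pj_)
  if (var_i <= 0 || var_j <= 0) return(1)
  cov <- sum(outer(i - mu_i, i - mu_j) * p)
  max(-1, min(1, cov / sqrt(var_i * var_j)))
}

#' Aggregate a GLCM feature over the 13 offsets
#'
#' Computes the feature for each offset GLCM and returns the unweighted
#' mean over non-empty offsets. This aggregate is the `GLCM_Correl` entry
#' of the feature vector.
#'
#' @param roi A [quantise()]d ROI.
#' @param feature Currently `"correlation"`.
#' @param offsets Integer matrix of offsets (rows), default all 13.
#' @return Scalar aggregate value.
#' @export
aggregate_glcm_feature <- function(roi, feature = "correlation",
                                   offsets = glcm_offsets()) {
  feature <- match.arg(feature, "correlation")
  vals <- apply(offsets, 1, function(off) {
    g <- glcm_for_offset(roi, off)
    if (g$empty) NA_real_ else glcm_correlation(g)
  })
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stopf("all GLCM offsets are empty for this ROI")
  mean(vals)
}
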