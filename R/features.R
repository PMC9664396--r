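#' Extract the radiomics feature vector for one scan
#'
#' Computes the two signature features plus a documented support set on a
#' preprocessed image/mask pair (intended spacing 1 x 1 x 2 mm, capped
#' intensities):
#' \describe{
#'   \item{SNS_s2v}{mesh surface area / volume (mm^-1), see
#'     [shape_metrics()].}
#'   \item{GLCM_Correl}{mean GLCM correlation over the 13 unique 3-D
#'     offsets at distance 1, 25-HU bins anchored at the in-mask minimum,
#'     see [aggregate_glcm_feature()].}
#'   \item{volume_mm3, surface_area_mm2, max_axial_diameter_mm}{shape
#'     support features.}
#'   \item{fo_mean, fo_sd, fo_skewness, fo_kurtosis, fo_entropy}{first-order
#'     statistics of in-mask HU; entropy (bits) over the same 25-HU bins;
#'     skewness/kurtosis are 0 for flat regions by convention.}
#' }
#'
#' @param volume An [image_volume()] (preprocessed).
#' @param mask Paired non-empty [segmentation_mask()].
#' @param bin_width HU bin width for quantisation (default 25).
#' @return A named numeric `feature_vector` with attribute
#'   `standardised = FALSE`.
#' @export
extract_features <- function(volume, mask, bin_width = 25) {
  check_pair(volume, mask)
  if (sum(mask$voxels) == 0L) stopf("cannot extract features: empty mask")
  sm <- shape_metrics(mask)
  roi <- quantise(volume, mask, bin_width)
  vals <- volume$voxels[mask$voxels != 0L]
  n <- length(vals)
  p <- tabulate(roi$levels[roi$levels > 0L], nbins = roi$K) / n
  p <- p[p > 0]
  fv <- c(SNS_s2v = sm$s2v_per_mm,
          GLCM_Correl = aggregate_glcm_feature(roi),
          volume_mm3 = sm$volume_mm3,
          surface_area_mm2 = sm$surface_area_mm2,
          max_axial_diameter_mm = sm$max_axial_diameter_mm,
          fo_mean = mean(vals),
          fo_sd = stats::sd(vals),
          fo_skewness = if (stats::sd(vals) > 0) e1071::skewness(vals) else 0,
          fo_kurtosis = if (stats::sd(vals) > 0) e1071::kurtosis(vals) else 0,
          fo_entropy = -sum(p * log2(p)))
  structure(fv, standardised = FALSE, class = "feature_vector")
}

#' Z-standardisation fitted on a training set
#'
#' `fit_standardiser()` estimates per-feature means and (sample) standard
#' deviations on training rows; `apply_standardiser()` transforms any
#' matrix with those *training* statistics, so held-out data never leaks
#' into the scaling. The training z-matrix has column means 0 and SDs 1.
#'
#' @param X Numeric matrix or data.frame of raw features (rows = scans),
#'   at least 2 rows.
#' @return `fit_standardiser()`: a `standardisation_params` list with
#'   `mean` and `sd`; `apply_standardiser()`: the z-matrix with attributes
#'   `standardised = TRUE` and `params`.
#' @export
fit_standardiser <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least 2 rows to fit a standardiser")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero))
    stopf("zero variance: %s", paste(colnames(X)[zero], collapse = ", "))
  structure(list(mean = mu, sd = sdv), class = "standardisation_params")
}

#' @rdname fit_standardiser
#' @param params A `standardisation_params` object.
#' @export
apply_standardiser <- function(params, X) {
  stopifnot(inherits(params, "standardisation_params"))
  X <- as.matrix(X)
  miss <- setdiff(names(params$mean), colnames(X))
  if (length(miss))
    stopf("matrix lacks feature(s): %s", paste(miss, collapse = ", "))
  X <- X[, names(params$mean), drop = FALSE]
  Z <- sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
  attr(Z, "standardised") <- TRUE
  attr(Z, "params") <- params
  Z
}

#' Extract features for many scans into a feature table
#'
#' @param pairs Named list of `list(image =, mask =)` pairs (names become
#'   `scan_id`).
#' @param bin_width HU bin width.
#' @return data.frame with `scan_id` plus one column per feature.
#' @export
extract_feature_table <- function(pairs, bin_width = 25) {
  rows <- lapply(pairs, function(p)
    as.numeric(extract_features(p$image, p$mask, bin_width)))
  fv1 <- extract_features(pairs[[1]]$image, pairs[[1]]$mask, bin_width)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- names(fv1)
  cbind(scan_id = if (is.null(names(pairs)))
    sprintf("scan_%03d", seq_along(pairs)) else names(pairs), out)
}
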