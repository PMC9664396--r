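# Published signature constants: LASSO log-odds weights of the two
# z-standardised features and the training-set Youden-optimal threshold.
LNRPV_COEF <- c(SNS_s2v = -0.5143257, GLCM_Correl = 0.1840902)
LNRPV_THRESHOLD <- -0.1991184

#' Compute the large-nodule radiomics predictive vector (LN-RPV)
#'
#' The LN-RPV is the weighted sum
#' `-0.5143257 * z(SNS_s2v) + 0.1840902 * z(GLCM_Correl)` of the two
#' z-standardised signature features; higher values indicate higher
#' malignancy risk (lower surface-to-volume ratio, i.e. rounder/larger
#' nodules, and stronger grey-level correlation both push the score up).
#'
#' @param z Named numeric vector or matrix of z-standardised features
#'   carrying attribute `standardised = TRUE` (as produced by
#'   [apply_standardiser()]); must contain `SNS_s2v` and `GLCM_Correl`.
#' @return Numeric score (one per row for matrices).
#' @examples
#' z <- matrix(c(-1, 0), 1, dimnames = list(NULL, c("SNS_s2v", "GLCM_Correl")))
#' attr(z, "standardised") <- TRUE
#' compute_ln_rpv(z)  # 0.5143257
#' @export
compute_ln_rpv <- function(z) {
  std <- attr(z, "standardised")
  if (is.null(std) || !isTRUE(std))
    stopf("compute_ln_rpv requires z-standardised features (see apply_standardiser)")
  if (is.null(dim(z))) z <- matrix(z, 1, dimnames = list(NULL, names(z)))
  miss <- setdiff(names(LNRPV_COEF), colnames(z))
  if (length(miss))
    stopf("feature vector lacks %s", paste(miss, collapse = ", "))
  drop(z[, names(LNRPV_COEF), drop = FALSE] %*% LNRPV_COEF)
}

#' Classify an LN-RPV score against the published threshold
#'
#' @param score Finite numeric LN-RPV score(s).
#' @param threshold Decision threshold (default the training-set
#'   Youden-optimal -0.1991184); the boundary is inclusive: a score equal
#'   to the threshold is called malignant.
#' @return Logical: `TRUE` = malignant call.
#' @export
classify_rpv <- function(score, threshold = LNRPV_THRESHOLD) {
  if (any(!is.finite(score))) stopf("scores must be finite")
  score >= threshold
}

#' K-means low/high risk groups on the LN-RPV
#'
#' `fit_risk_clusters()` runs 1-D 2-means (25 restarts) on training
#' scores; the cluster with the larger centroid is "high". Held-out scores
#' are assigned by nearest centroid - equivalently against the centroid
#' midpoint - with ties going to "high".
#'
#' @param training_scores Numeric vector with at least 2 distinct values.
#' @param seed Integer RNG seed for the restarts.
#' @return A `risk_clusters` list: `centroids` (low, high), `boundary`
#'   (midpoint), `seed`.
#' @export
fit_risk_clusters <- function(training_scores, seed = 1L) {
  x <- training_scores[is.finite(training_scores)]
  if (length(unique(x)) < 2L)
    stopf("risk clustering needs at least 2 distinct scores")
  km <- with_seed(seed, stats::kmeans(matrix(x), centers = 2L, nstart = 25L))
  cen <- sort(as.numeric(km$centers))
  structure(list(centroids = c(low = cen[1], high = cen[2]),
                 boundary = mean(cen), seed = as.integer(seed)),
            class = "risk_clusters")
}

#' @rdname fit_risk_clusters
#' @param score Numeric score(s) to assign.
#' @param clusters A `risk_clusters` object.
#' @return `assign_risk()`: character vector `"low"`/`"high"`.
#' @export
assign_risk <- function(score, clusters) {
  stopifnot(inherits(clusters, "risk_clusters"))
  ifelse(score >= clusters$boundary, "high", "low")
}
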