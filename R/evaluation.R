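#' ROC curve and AUC with bootstrap confidence interval
#'
#' The AUC is the normalised Mann-Whitney statistic with half credit for
#' ties, so ordinal scores (e.g. a radiologist's 1-5 scale) are handled
#' exactly. The 95% CI is a percentile bootstrap resampling scans (or
#' patients, when `patient_id` is given - multiple scans per patient then
#' move together) with replacement.
#'
#' @param scores Numeric or ordinal scores, higher = more malignant.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @param bootstrap_B Bootstrap iterations (default 1000; 0 skips the CI).
#' @param seed Integer RNG seed for the bootstrap.
#' @param patient_id Optional resampling unit identifiers.
#' @return A `roc_result` list: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `ci` (length 2), `bootstrap_B`, `seed`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), bootstrap_B = 0)$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, bootstrap_B = 1000L, seed = 1L,
                    patient_id = NULL) {
  labels <- as.integer(labels)
  check_two_classes(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  auc <- auc_mw(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_B > 0) {
    ci <- with_seed(seed, {
      stats_b <- replicate(bootstrap_B, {
        idx <- bootstrap_indices(length(scores), patient_id)
        lb <- labels[idx]
        if (length(unique(lb)) < 2L) NA_real_ else auc_mw(scores[idx], lb)
      })
      stats::quantile(stats_b, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    })
  }
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, ci = ci, bootstrap_B = bootstrap_B,
                 seed = as.integer(seed)),
            class = "roc_result")
}

# Mann-Whitney AUC with half credit for ties, via the rank formula.
auc_mw <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

bootstrap_indices <- function(n, patient_id) {
  if (is.null(patient_id)) return(sample.int(n, n, replace = TRUE))
  ids <- unique(patient_id)
  pick <- sample(ids, length(ids), replace = TRUE)
  unlist(lapply(pick, function(p) which(patient_id == p)), use.names = FALSE)
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stopf("both outcome classes must be present")
  invisible(TRUE)
}

#' Youden-optimal cutpoint
#'
#' Evaluates every observed score as a candidate threshold (positive call
#' when score >= threshold) and returns the one maximising the Youden
#' index (sensitivity + specificity - 1); among tied maximisers the
#' smallest threshold is returned. A warning is emitted when the best
#' achievable Youden index is not positive (scores anti-correlated with
#' the outcome).
#'
#' @inheritParams roc_auc
#' @return A `cutpoint_result` list: `threshold`, `youden`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutpoint <- function(scores, labels) {
  labels <- as.integer(labels)
  check_two_classes(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t)
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1,
    numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]
  if (max(j) <= 0)
    warnf("maximum Youden index is not positive (%.3f): scores may be inverted",
          max(j))
  structure(list(threshold = cand[best], youden = j[best],
                 sensitivity = mean(scores[labels == 1] >= cand[best]),
                 specificity = mean(scores[labels == 0] < cand[best])),
            class = "cutpoint_result")
}

#' Confusion-matrix performance metrics
#'
#' Standard binary metrics with a Wilson 95% CI for accuracy. Rates with a
#' zero denominator are reported as `NA` (not available), never as 0.
#'
#' @param predictions Binary predictions (0/1 or logical).
#' @param labels Binary reference labels of the same length.
#' @return A `confusion_metrics` list: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `accuracy_ci`, `sensitivity`, `specificity`, `ppv`, `npv`, `f1`.
#' @export
confusion_metrics <- function(predictions, labels) {
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  if (length(predictions) != length(labels))
    stopf("predictions/labels length mismatch")
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  n <- tp + fp + fn + tn
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- safe_div(tp, tp + fn)
  ppv <- safe_div(tp, tp + fp)
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / n,
                 accuracy_ci = wilson_ci((tp + tn) / n, n),
                 sensitivity = sens,
                 specificity = safe_div(tn, tn + fp),
                 ppv = ppv, npv = safe_div(tn, tn + fn), f1 = f1),
            class = "confusion_metrics")
}

wilson_ci <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

#' DeLong test for two paired ROC curves
#'
#' Two-sided comparison of two AUCs computed on the same cases, using the
#' placement-value covariance estimator of DeLong, DeLong and
#' Clarke-Pearson.
#'
#' @param scores_a,scores_b Paired scores on identical cases.
#' @param labels Binary labels, both classes present.
#' @return A `delong_result` list: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  check_two_classes(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stopf("scores must be paired with labels (equal lengths)")
  pos <- labels == 1
  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]
    m <- length(x); n <- length(y)
    # V10[i] = P(X_i > Y) + 0.5 P(X_i = Y); V01[j] likewise
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0 || d == 0) {
    z <- 0; p <- 1
    if (d != 0) { z <- sign(d) * Inf; p <- 0 }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p),
            class = "delong_result")
}

#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC for
#' two paired measurement methods, from the two-way ANOVA mean squares
#' (McGraw & Wong case 2A), with the F-based p-value for the null
#' ICC = 0.
#'
#' @param x,y Paired measurements, n >= 3.
#' @return An `icc_result` list: `icc`, `p`, and the mean squares `msr`
#'   (rows), `msc` (columns), `mse`.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) stopf("paired measurements required")
  n <- length(x)
  if (n < 3L) stopf("ICC needs at least 3 pairs")
  m <- cbind(x, y)
  k <- 2L
  if (stats::var(as.numeric(m)) == 0)
    stopf("ICC undefined: zero total variance")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fval <- msr / mse
  p <- stats::pf(fval, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, p = p, msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and chi-square p-value, as
#' used to probe scan-vendor effects on a non-normally distributed score.
#' Thin wrapper over [stats::kruskal.test()].
#'
#' @param values Numeric values.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dice overlap between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param mask_a,mask_b [segmentation_mask()]s (or 0/1 arrays) on the
#'   same grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "segmentation_mask")) mask_a$voxels else mask_a
  b <- if (inherits(mask_b, "segmentation_mask")) mask_b$voxels else mask_b
  if (!identical(dim(a), dim(b)))
    stopf("grid mismatch: %s vs %s", paste(dim(a), collapse = "x"),
          paste(dim(b), collapse = "x"))
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}
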