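# Independent oracles used across the suite. Each is a deliberately naive
# implementation (brute force, enumeration, closed form) kept free of the
# package's own code paths.

# Brute-force GLCM: O(N^2)-style enumeration over every in-mask voxel and
# its partner at `offset`, then symmetrisation.
brute_force_glcm <- function(levels, offset, K) {
  counts <- matrix(0, K, K)
  d <- dim(levels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- levels[i, j, k]
    if (a == 0L) next
    ii <- i + offset[1]; jj <- j + offset[2]; kk <- k + offset[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
      next
    b <- levels[ii, jj, kk]
    if (b == 0L) next
    counts[a, b] <- counts[a, b] + 1
  }
  counts + t(counts)
}

# Exhaustive optimal 1-D 2-partition minimising within-cluster sum of
# squares: scan every split point of the sorted values.
exhaustive_two_partition <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- list(ss = Inf)
  for (s in 1:(n - 1)) {
    lo <- xs[1:s]; hi <- xs[(s + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best$ss)
      best <- list(ss = ss, centroids = c(mean(lo), mean(hi)), split = s)
  }
  best
}

# Proximal-gradient (ISTA) solver for L1-penalised logistic regression with
# an unpenalised intercept, matching glmnet's objective
# (1/n) sum logloss + lambda * ||beta||_1.
prox_grad_lasso_logistic <- function(X, y, lambda, iters = 20000,
                                     step = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(step)) step <- 4 / (max(colSums(X^2)) / n + 1)
  b0 <- 0; b <- rep(0, p)
  for (it in seq_len(iters)) {
    eta <- b0 + drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    g0 <- mean(mu - y)
    g <- drop(crossprod(X, mu - y)) / n
    b0 <- b0 - step * g0
    bn <- b - step * g
    b <- sign(bn) * pmax(abs(bn) - step * lambda, 0)
  }
  list(intercept = b0, beta = b)
}

# Youden cutpoint by exhaustive threshold scan over a fine grid extended
# beyond the data range.
brute_force_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores, min(scores) - 1, max(scores) + 1)))
  j <- sapply(cand, function(t)
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1)
  list(threshold = cand[which.max(j)], youden = max(j))
}

# AUC by explicit enumeration of all positive/negative pairs.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

make_flat_sphere <- function(r = 8, spacing = c(1, 1, 1), seed = 1) {
  generate_phantom(phantom_spec(radius_mm = r, spacing_mm = spacing,
                                seed = seed))
}

# Random blob-ish quantised ROI on a small grid for GLCM property tests.
random_roi <- function(dim3 = c(12, 12, 8), K_target = 6, seed = 1) {
  withr::with_seed(seed, {
    vox <- array(sample.int(K_target * 25, prod(dim3), replace = TRUE) - 1,
                 dim = dim3)
    ctr <- dim3 / 2
    idx <- which(array(TRUE, dim3), arr.ind = TRUE)
    d2 <- rowSums(sweep(idx, 2, ctr)^2)
    msk <- array(as.integer(d2 <= (min(dim3) / 2.2)^2), dim = dim3)
    vol <- image_volume(vox, c(1, 1, 1))
    mask <- segmentation_mask(msk, c(1, 1, 1))
    quantise(vol, mask)
  })
}
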