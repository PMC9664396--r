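#' Grouped, stratified training/test split
#'
#' Allocates patients (never individual scans) to training and test sets,
#' so that all scans of a patient land in one set and no leakage occurs,
#' while stratifying on the patient-level malignancy label to keep the
#' malignant proportion equal across sets.
#'
#' @param cohort data.frame with `patient_id` and `outcome` columns
#'   (`"benign"`/`"malignant"`; a patient's label is shared by all of
#'   their scans).
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer RNG seed.
#' @return A `split_result` list: `train_idx`/`test_idx` (row indices into
#'   `cohort`), `train_patients`/`test_patients`, `fraction`, `seed`.
#' @export
grouped_stratified_split <- function(cohort, fraction = 0.7, seed = 1L) {
  stopifnot(all(c("patient_id", "outcome") %in% names(cohort)),
            fraction > 0, fraction < 1)
  pat <- unique(cohort[, c("patient_id", "outcome")])
  dup <- duplicated(pat$patient_id)
  if (any(dup)) pat <- pat[!dup, ]   # label shared per patient by contract
  classes <- split(pat$patient_id, pat$outcome)
  if (length(classes) < 2L || any(lengths(classes) < 2L))
    stopf("need at least 2 patients in each outcome class to stratify")
  train_patients <- with_seed(seed, unlist(lapply(classes, function(ids) {
    n_tr <- round(length(ids) * fraction)
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    sample(ids, n_tr)
  }), use.names = FALSE))
  in_train <- cohort$patient_id %in% train_patients
  structure(list(train_idx = which(in_train),
                 test_idx = which(!in_train),
                 train_patients = sort(train_patients),
                 test_patients = sort(setdiff(pat$patient_id,
                                              train_patients)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_result")
}

#' Univariable logistic screen with Benjamini-Hochberg correction
#'
#' Fits one single-predictor maximum-likelihood logistic regression per
#' column of `X` against the binary outcome, reports Wald z-test p-values,
#' odds ratios with 95% CIs, applies Benjamini-Hochberg step-up adjustment
#' across all converged columns as one family, and flags selection at
#' adjusted p below `alpha`. Columns with failed or degenerate fits
#' (perfect separation) are excluded with a warning.
#'
#' @param X Numeric matrix or data.frame of predictors.
#' @param y Binary outcome (0/1 or logical), both classes present.
#' @param alpha Selection level on the adjusted p-value (default 0.05).
#' @return A `screen_table` data.frame: `feature`, `beta`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `p_adj`, `selected`, `converged`.
#' @export
univariable_screen <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("outcome has a single class")
  if (nrow(X) != length(y)) stopf("X and y lengths differ")
  nm <- colnames(X)
  if (is.null(nm)) nm <- sprintf("x%d", seq_len(ncol(X)))
  fits <- lapply(seq_len(ncol(X)), function(j) {
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(),
                                       data = data.frame(y = y, x = X[, j])))
    s <- summary(fit)$coefficients
    conv <- fit$converged && nrow(s) == 2L && s[2, 2] < 100
    list(beta = s[2, 1], se = s[2, 2], p = s[2, 4], converged = conv)
  })
  beta <- vapply(fits, `[[`, numeric(1), "beta")
  se <- vapply(fits, `[[`, numeric(1), "se")
  p <- vapply(fits, `[[`, numeric(1), "p")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!conv))
    warnf("excluding %d non-converged feature(s) from the screen: %s",
          sum(!conv), paste(nm[!conv], collapse = ", "))
  p_adj <- rep(NA_real_, length(p))
  p_adj[conv] <- stats::p.adjust(p[conv], method = "BH")
  data.frame(feature = nm, beta = beta, or = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = p, p_adj = p_adj,
             selected = !is.na(p_adj) & p_adj < alpha,
             converged = conv, row.names = NULL)
}

#' Cross-validated LASSO signature fit (lambda.1se rule)
#'
#' L1-penalised logistic regression over a log-spaced lambda grid (about
#' 100 values down a factor 1e-4 from the smallest all-zero lambda), with
#' stratified k-fold cross-validation by binomial deviance. The selected
#' penalty is the largest lambda whose CV error is within one standard
#' error of the minimum (`lambda.1se`); the non-zero coefficients at that
#' penalty define the signature's linear score. Predictors are assumed
#' pre-standardised (no internal rescaling) and the intercept is never
#' penalised.
#'
#' @param X_z Z-standardised numeric feature matrix.
#' @param y Binary outcome, at least `folds` observations per class.
#' @param folds CV folds (default 10).
#' @param seed Integer RNG seed controlling the fold assignment.
#' @return A `lasso_fit` list: `lambda` (grid), `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `coefficients` (non-zero, named, no
#'   intercept), `intercept`, `score_fun(X)`, `seed`.
#' @export
lasso_signature <- function(X_z, y, folds = 10L, seed = 1L) {
  X_z <- as.matrix(X_z)
  y <- as.integer(y)
  if (min(table(y)) < folds)
    stopf("need at least %d observations per class for %d-fold CV",
          folds, folds)
  foldid <- with_seed(seed, stratified_folds(y, folds))
  cv <- glmnet::cv.glmnet(X_z, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          standardize = FALSE, nlambda = 100,
                          lambda.min.ratio = 1e-4, thresh = 1e-10)
  cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))
  nz <- cf[-1, 1][cf[-1, 1] != 0]
  if (!length(nz))
    warnf("all-zero solution at lambda.1se; the signature is empty")
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 coefficients = nz, intercept = cf[1, 1],
                 score_fun = function(X) {
                   X <- as.matrix(X)[, names(nz), drop = FALSE]
                   drop(X %*% nz)
                 },
                 glmnet_fit = cv, seed = as.integer(seed)),
            class = "lasso_fit")
}

# Class-stratified fold labels 1..k.
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Multivariable logistic regression with Wald inference
#'
#' Maximum-likelihood multivariable logistic fit. Character/factor columns
#' are dummy-coded with the most common level as the reference. Exact rank
#' deficiency is an error naming the collinear columns.
#'
#' @param X data.frame or matrix of predictors.
#' @param y Binary outcome.
#' @return A `multivariable_fit` list: `table` (data.frame with `term`,
#'   `beta`, `or`, `ci_lo`, `ci_hi`, `p`), `fit` (the glm object).
#' @export
multivariable_fit <- function(X, y) {
  df <- as.data.frame(X, stringsAsFactors = FALSE)
  y <- as.integer(y)
  if (nrow(df) <= ncol(df)) stopf("need more observations than predictors")
  for (nmc in names(df)) {
    if (is.character(df[[nmc]]) || is.factor(df[[nmc]])) {
      tabl <- sort(table(as.character(df[[nmc]])), decreasing = TRUE)
      df[[nmc]] <- stats::relevel(factor(as.character(df[[nmc]]),
                                         levels = names(tabl)),
                                  ref = names(tabl)[1])
    }
  }
  fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                     data = cbind(df, y = y)))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("rank-deficient design; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  s <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(s)[-1], beta = s[-1, 1],
                    or = exp(s[-1, 1]),
                    ci_lo = exp(s[-1, 1] - 1.96 * s[-1, 2]),
                    ci_hi = exp(s[-1, 1] + 1.96 * s[-1, 2]),
                    p = s[-1, 4], row.names = NULL)
  structure(list(table = tab, fit = fit), class = "multivariable_fit")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the linear
#' regression of predictor j on all other predictors. Exact collinearity
#' is reported as `Inf` with a warning.
#'
#' @param X Numeric matrix or data.frame with at least 2 columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stopf("VIF needs at least 2 predictors")
  nm <- colnames(X)
  if (is.null(nm)) nm <- sprintf("x%d", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - ssr / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- nm
  if (any(is.infinite(out)))
    warnf("exact collinearity: infinite VIF for %s",
          paste(nm[is.infinite(out)], collapse = ", "))
  out
}

#' Develop a radiomics signature from a feature table
#'
#' The full development workflow on training data: z-standardisation,
#' univariable screen with B-H selection, cross-validated LASSO at
#' lambda.1se on the selected features, Youden threshold on the training
#' scores, and K-means risk clusters.
#'
#' @param X Raw feature matrix (training rows).
#' @param y Binary training outcome.
#' @param folds,seed Passed to [lasso_signature()].
#' @param alpha Screen selection level.
#' @return A `signature_fit` list: `standardiser`, `screen`, `lasso`,
#'   `threshold` (training Youden cutpoint on the fitted score),
#'   `clusters`, and `score_fun(raw X) -> score`.
#' @export
develop_signature <- function(X, y, folds = 10L, seed = 1L, alpha = 0.05) {
  std <- fit_standardiser(X)
  Z <- apply_standardiser(std, X)
  screen <- univariable_screen(Z, y, alpha = alpha)
  keep <- screen$feature[screen$selected]
  if (length(keep) < 2L)
    stopf("fewer than 2 features pass the univariable screen")
  fit <- lasso_signature(Z[, keep, drop = FALSE], y, folds = folds,
                         seed = seed)
  score_fun <- function(Xnew) {
    Zn <- apply_standardiser(std, Xnew)
    fit$score_fun(Zn)
  }
  scores <- score_fun(X)
  cut <- youden_cutpoint(scores, y)
  structure(list(standardiser = std, screen = screen, lasso = fit,
                 threshold = cut$threshold,
                 clusters = fit_risk_clusters(scores, seed = seed),
                 score_fun = score_fun),
            class = "signature_fit")
}
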