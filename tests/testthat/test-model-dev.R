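test_that("split is grouped by patient, stratified, and deterministic", {
  co <- simulate_cohort(cohort_spec(n_patients = 100, scans_per_patient = 1,
                                    prevalence = 0.5, seed = 6))
  sp <- grouped_stratified_split(co, 0.7, seed = 3)
  expect_equal(length(sp$train_idx) + length(sp$test_idx), nrow(co))
  expect_length(intersect(sp$train_patients, sp$test_patients), 0)
  prev_tr <- mean(co$outcome[sp$train_idx] == "malignant")
  prev_te <- mean(co$outcome[sp$test_idx] == "malignant")
  expect_lt(abs(prev_tr - prev_te), 0.05)
  sp2 <- grouped_stratified_split(co, 0.7, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
})

test_that("multi-scan patients never straddle the split", {
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_spec(n_patients = 60,
                                      scans_per_patient = 3, seed = seed))
    sp <- grouped_stratified_split(co, 0.7, seed = seed)
    tr_p <- unique(co$patient_id[sp$train_idx])
    te_p <- unique(co$patient_id[sp$test_idx])
    expect_length(intersect(tr_p, te_p), 0)
    # every scan of a 3-scan patient sits in one set
    multi <- names(which(table(co$patient_id) == 3))
    for (p in head(multi, 3)) {
      rows <- which(co$patient_id == p)
      expect_true(all(rows %in% sp$train_idx) || all(rows %in% sp$test_idx))
    }
  }
  expect_error(grouped_stratified_split(
    data.frame(patient_id = c("a", "b"), outcome = c("benign", "benign")),
    0.7, 1), "2 patients")
})

test_that("B-H adjustment follows the step-up formula", {
  scr <- univariable_screen(
    matrix(rnorm(400), 100, 4, dimnames = list(NULL, letters[1:4])),
    rbinom(100, 1, 0.5))
  # hand-checkable p-value set via direct p.adjust comparison
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  expect_true(all(scr$p_adj >= scr$p - 1e-12, na.rm = TRUE))
  ranks <- order(scr$p)
  expect_true(all(diff(scr$p_adj[ranks]) >= -1e-12))
})

test_that("univariable screen controls type-I error under the null", {
  sim <- simulate_features(2000, 50, beta = numeric(0), seed = 31)
  scr <- univariable_screen(sim$X, sim$y)
  rate <- mean(scr$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 50)
  expect_lt(abs(rate - 0.05), 3 * se)
  expect_false(any(scr$selected))  # B-H keeps the null family clean
})

test_that("univariable screen recovers a known coefficient", {
  sim <- simulate_features(5000, 3, beta = c(0.8), seed = 32)
  scr <- univariable_screen(sim$X, sim$y)
  expect_lt(abs(scr$beta[1] - 0.8), 0.1)
  expect_true(scr$selected[1])
  expect_equal(scr$or, exp(scr$beta))
})

test_that("perfectly separating features are flagged and excluded", {
  y <- rep(0:1, each = 20)
  X <- cbind(sep = y * 2 - 1 + 0.01 * seq_len(40),
             ok = rnorm(40))
  expect_warning(scr <- univariable_screen(X, y), "non-converged")
  expect_false(scr$converged[1])
  expect_true(is.na(scr$p_adj[1]))
})

test_that("LASSO at high lambda is empty; lambda.1se meets its contract", {
  sim <- simulate_features(400, 10, beta = c(1, -1), seed = 33)
  Z <- scale(sim$X)
  fit <- lasso_signature(Z, sim$y, seed = 2)
  expect_gte(fit$lambda_1se, fit$lambda_min)
  # the 1se rule: cv error at lambda_1se within one SE of the minimum
  i_min <- which.min(fit$cvm)
  i_1se <- which(fit$lambda == fit$lambda_1se)
  expect_lte(fit$cvm[i_1se], fit$cvm[i_min] + fit$cvsd[i_min] + 1e-12)
  # largest penalty of the grid shrinks everything to zero
  cf_top <- as.matrix(stats::coef(fit$glmnet_fit$glmnet.fit,
                                  s = max(fit$lambda)))
  expect_true(all(cf_top[-1, 1] == 0))
  # the induced score function reproduces the linear predictor
  s <- fit$score_fun(Z)
  expect_equal(s, drop(Z[, names(fit$coefficients), drop = FALSE] %*%
                         fit$coefficients))
})

test_that("LASSO coefficients match a proximal-gradient oracle", {
  sim <- simulate_features(300, 5, beta = c(1, -0.8), seed = 34)
  Z <- scale(sim$X)
  lam <- 0.05
  gfit <- glmnet::glmnet(Z, sim$y, family = "binomial", lambda = lam,
                         standardize = FALSE, thresh = 1e-12)
  oracle <- prox_grad_lasso_logistic(Z, sim$y, lam)
  cf <- as.matrix(stats::coef(gfit))
  expect_lt(max(abs(cf[-1, 1] - oracle$beta)), 1e-4)
  expect_lt(abs(cf[1, 1] - oracle$intercept), 1e-4)
})

test_that("multivariable fit recovers coefficients and dummy codes", {
  sim <- simulate_features(5000, 2, beta = c(0.5, -0.5), seed = 35)
  fit <- multivariable_fit(as.data.frame(sim$X), sim$y)
  expect_lt(abs(fit$table$beta[1] - 0.5), 0.1)
  expect_lt(abs(fit$table$beta[2] + 0.5), 0.1)
  # single-predictor multivariable fit equals the univariable screen
  scr <- univariable_screen(sim$X[, 1, drop = FALSE], sim$y)
  uni <- multivariable_fit(data.frame(feat_001 = sim$X[, 1]), sim$y)
  expect_equal(uni$table$beta, scr$beta[1], tolerance = 1e-8)
  # most common level becomes the reference
  withr::with_seed(36, {
    dens <- sample(c("solid", "subsolid", "GGO"), 600, TRUE,
                   prob = c(0.7, 0.23, 0.07))
    y <- rbinom(600, 1, 0.5)
    mv <- multivariable_fit(data.frame(density = dens), y)
    expect_setequal(mv$table$term,
                    c("densitysubsolid", "densityGGO"))
  })
})

test_that("rank-deficient designs are rejected naming the column", {
  X <- data.frame(a = rnorm(50), b = rnorm(50))
  X$c <- X$a + X$b
  expect_error(multivariable_fit(X, rbinom(50, 1, 0.5)), "collinear.*c")
})

test_that("VIF follows the 1/(1-R2) closed form", {
  withr::with_seed(37, {
    # mutually orthogonal (and mean-zero) columns -> VIF exactly 1
    q <- unclass(stats::poly(1:100, 3))
    expect_equal(unname(vif(q)), rep(1, 3), tolerance = 1e-8)
    # x2 = x1 + noise tuned to R2 ~ 0.9 -> VIF ~ 10
    x1 <- rnorm(4000)
    x2 <- x1 + rnorm(4000, sd = 1 / 3)
    v <- vif(cbind(x1 = x1, x2 = x2, x3 = rnorm(4000)))
    expect_lt(abs(v[["x2"]] - 10), 1.5)
    # duplicated column -> infinite with warning
    expect_warning(v2 <- vif(cbind(a = x1, b = x1, c = rnorm(4000))),
                   "collinearity")
    expect_true(is.infinite(v2[["a"]]) && is.infinite(v2[["b"]]))
  })
})

test_that("a derived predictor inflates both VIFs above 10", {
  withr::with_seed(38, {
    herderish <- runif(500, 0, 100)
    derived <- stats::plogis((herderish - 50) / 10) * 100 +
      rnorm(500, sd = 2)
    v <- vif(cbind(a = herderish, b = derived, c = rnorm(500)))
    expect_gt(v[["a"]], 10)
    expect_gt(v[["b"]], 10)
  })
})

test_that("screen + LASSO recovers a two-feature signature", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- simulate_features(2000, 50, beta = c(1, -1), seed = 100 + seed)
    sig <- try(develop_signature(sim$X, sim$y, seed = seed), silent = TRUE)
    if (inherits(sig, "try-error")) next
    nz <- names(sig$lasso$coefficients)
    if (all(c("feat_001", "feat_002") %in% nz)) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
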