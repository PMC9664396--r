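test_that("AUC equals pairwise enumeration, with tie credit", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), bootstrap_B = 0)
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), bootstrap_B = 0)$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1),
                       bootstrap_B = 0)$auc, 0.5)
  withr::with_seed(41, for (i in 1:5) {
    n <- 40
    sc <- sample(seq(0, 1, by = 0.1), n, TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(sc, y, bootstrap_B = 0)$auc, pairwise_auc(sc, y))
  })
  expect_error(roc_auc(1:4, c(1, 1, 1, 1), bootstrap_B = 0), "both")
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(42, {
    sc <- rnorm(60); y <- rbinom(60, 1, 0.5)
    a0 <- roc_auc(sc, y, bootstrap_B = 0)$auc
    for (f in list(function(x) 3 * x + 2, exp, function(x) x^3))
      expect_equal(roc_auc(f(sc), y, bootstrap_B = 0)$auc, a0)
  })
})

test_that("bootstrap CI brackets the point estimate deterministically", {
  withr::with_seed(43, {
    sc <- c(rnorm(40), rnorm(40, 1)); y <- rep(0:1, each = 40)
  })
  r1 <- roc_auc(sc, y, bootstrap_B = 200, seed = 7)
  r2 <- roc_auc(sc, y, bootstrap_B = 200, seed = 7)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$auc); expect_gte(r1$ci[2], r1$auc)
  # patient-level resampling keeps a patient's scans together and works
  pid <- rep(1:40, each = 2)
  rp <- roc_auc(sc, y, bootstrap_B = 50, seed = 1, patient_id = pid)
  expect_true(is.finite(rp$ci[1]) && rp$ci[1] < rp$ci[2])
})

test_that("Youden cutpoint matches the exhaustive threshold scan", {
  cut <- youden_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(cut$youden, 1)
  expect_gt(cut$threshold, 2); expect_lte(cut$threshold, 3)
  withr::with_seed(44, for (i in 1:10) {
    sc <- sample(seq(0, 2, by = 0.2), 30, TRUE)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    ours <- suppressWarnings(youden_cutpoint(sc, y))
    oracle <- brute_force_youden(sc, y)
    expect_equal(ours$youden, oracle$youden, tolerance = 1e-12)
    expect_equal(ours$sensitivity + ours$specificity - 1, ours$youden)
  })
  expect_warning(youden_cutpoint(c(4, 3, 2, 1), c(0, 0, 1, 1)),
                 "inverted")
})

test_that("confusion metrics reproduce printed reader performance", {
  # counts reconstructed from sensitivity 0.50 / specificity 0.91 at
  # 158 malignant / 94 benign test scans
  pred <- rep(c(1, 1, 0, 0), c(79, 8, 79, 86))
  lab <- rep(c(1, 0, 1, 0), c(79, 8, 79, 86))
  cm <- confusion_metrics(pred, lab)
  expect_equal(round(100 * cm$accuracy), 65)
  expect_equal(round(cm$f1, 2), 0.64)
  expect_equal(round(cm$sensitivity, 2), 0.50)
  expect_equal(round(cm$specificity, 2), 0.91)
  expect_equal(round(cm$ppv, 2), 0.91)
  expect_equal(round(cm$npv, 2), 0.52)
  expect_equal(round(100 * cm$accuracy_ci), c(59, 71))
})

test_that("degenerate confusion cases use NA, not zero", {
  all_right <- confusion_metrics(c(1, 1, 0), c(1, 1, 0))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$f1, 1)
  none_pos <- confusion_metrics(c(0, 0, 0), c(1, 0, 0))
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$specificity, 1)
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("DeLong test is symmetric and null on identical curves", {
  withr::with_seed(45, {
    y <- rep(0:1, each = 30)
    a <- rnorm(60) + y; b <- rnorm(60) + 0.5 * y
  })
  same <- delong_test(a, a, y)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  ab <- delong_test(a, b, y); ba <- delong_test(b, a, y)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$auc_a, roc_auc(a, y, bootstrap_B = 0)$auc)
})

test_that("DeLong agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(46, {
    y <- rep(0:1, each = 40)
    a <- rnorm(80) + 0.8 * y; b <- rnorm(80) + 0.4 * y
  })
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("ICC(A,1) matches the mean-squares decomposition by hand", {
  # printed 6-pair toy table
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  r <- icc_agreement(x, y)
  n <- 6; k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  icc_hand <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(r$icc, icc_hand, tolerance = 1e-10)
  expect_equal(icc_agreement(x, x)$icc, 1)
  # agreement penalises a systematic shift below the Pearson correlation
  shifted <- icc_agreement(x, x + 10)
  expect_lt(shifted$icc, stats::cor(x, x + 10))
  expect_lte(r$icc, 1)
})

test_that("ICC equals Pearson r for equal-mean equal-variance raters", {
  withr::with_seed(47, {
    x <- rnorm(300)
    y <- 0.7 * x + rnorm(300, sd = 0.5)
    y <- (y - mean(y)) / sd(y) * sd(x) + mean(x)  # exact mean/var match
  })
  r <- icc_agreement(x, y)
  expect_equal(r$icc, stats::cor(x, y), tolerance = 0.02)
  expect_error(icc_agreement(c(1, 1, 1), c(1, 1, 1)), "zero total variance")
})

test_that("Kruskal-Wallis handles ties and identical groups", {
  kw <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  # hand-ranked fixed instance with ties, against the base implementation
  v <- c(1, 2, 2, 3, 5, 5, 5, 7)
  g <- c("a", "a", "b", "b", "a", "b", "c", "c")
  ours <- kruskal_wallis(v, g)
  ref <- stats::kruskal.test(v, factor(g))
  expect_equal(ours$H, unname(ref$statistic))
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Dice matches the closed form and its edge cases", {
  a <- array(0L, c(5, 5, 4)); b <- a
  a[1:2, , ] <- 1L; b[1:2, , ] <- 1L
  expect_equal(dice_score(a, b), 1)
  b2 <- array(0L, c(5, 5, 4)); b2[4:5, , ] <- 1L
  expect_equal(dice_score(a, b2), 0)
  # |A| = |B| = 100, overlap 50
  a3 <- array(0L, c(10, 10, 2)); a3[seq_len(100)] <- 1L
  b3 <- array(0L, c(10, 10, 2)); b3[51:150] <- 1L
  expect_equal(sum(a3), 100); expect_equal(sum(b3), 100)
  expect_equal(dice_score(a3, b3), 0.5)
  expect_equal(dice_score(b3, a3), 0.5)  # symmetric
  expect_equal(dice_score(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  expect_error(dice_score(a, array(0L, c(4, 5, 4))), "mismatch")
})
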