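test_that("sphere phantom volume matches the analytic sphere", {
  spec <- phantom_spec(radius_mm = 10, spacing_mm = c(1, 1, 1))
  ph <- generate_phantom(spec)
  vol <- sum(ph$mask$voxels) * prod(spec$spacing_mm)
  expect_lt(abs(vol / (4 / 3 * pi * 1000) - 1), 0.05)
  # convergence: finer grid tightens the error below 2%
  fine <- generate_phantom(phantom_spec(radius_mm = 10,
                                        spacing_mm = c(0.5, 0.5, 0.5)))
  vol_fine <- sum(fine$mask$voxels) * 0.125
  expect_lt(abs(vol_fine / (4 / 3 * pi * 1000) - 1), 0.02)
})

test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(radius_mm = 8, noise_sd_hu = 30,
                       texture_correlation_length_mm = 3, seed = 42L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  c <- generate_phantom(phantom_spec(radius_mm = 8, noise_sd_hu = 30,
                                     texture_correlation_length_mm = 3,
                                     seed = 43L))
  expect_false(identical(a$image$voxels, c$image$voxels))
})

test_that("spiculated phantoms have larger surface area than spheres", {
  sphere <- generate_phantom(phantom_spec(radius_mm = 8,
                                          spacing_mm = c(1, 1, 1)))
  spic <- generate_phantom(phantom_spec(shape_kind = "spiculated",
                                        radius_mm = 8, n_spikes = 12,
                                        spacing_mm = c(1, 1, 1)))
  a_sphere <- shape_metrics(sphere$mask)$surface_area_mm2
  a_spic <- shape_metrics(spic$mask)$surface_area_mm2
  expect_gt(a_spic, a_sphere)
  expect_gt(sum(spic$mask$voxels), sum(sphere$mask$voxels))
})

test_that("oversize shapes are rejected naming the offending dimension", {
  expect_error(phantom_spec(radius_mm = 40, grid_shape = c(20, 64, 64),
                            spacing_mm = c(1, 1, 1)),
               "axis 1")
  expect_error(phantom_spec(texture_correlation_length_mm = -1),
               "non-negative")
})

test_that("texture correlation length controls neighbour dependence", {
  base <- list(radius_mm = 12, noise_sd_hu = 50, spacing_mm = c(1, 1, 1),
               seed = 3L)
  white <- generate_textured_phantom(do.call(phantom_spec,
    c(base, texture_correlation_length_mm = 0)))
  smooth <- generate_textured_phantom(do.call(phantom_spec,
    c(base, texture_correlation_length_mm = 5)))
  expect_gt(sum(white$mask$voxels), 1e4 / 2)  # enough voxels for stability
  c_white <- aggregate_glcm_feature(quantise(white$image, white$mask))
  c_smooth <- aggregate_glcm_feature(quantise(smooth$image, smooth$mask))
  expect_lt(abs(c_white), 0.1)
  expect_gt(c_smooth, c_white)
  # constant fill triggers the flat-region convention downstream
  flat <- generate_phantom(phantom_spec(radius_mm = 8, noise_sd_hu = 0))
  expect_identical(quantise(flat$image, flat$mask)$K, 1L)
})

test_that("simulated cohorts hit the target prevalence and share labels", {
  co <- simulate_cohort(cohort_spec(n_patients = 2000, scans_per_patient = 1,
                                    prevalence = 0.5, seed = 10))
  prev <- mean(co$outcome == "malignant")
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(prev - 0.5), 3 * se)

  co2 <- simulate_cohort(cohort_spec(n_patients = 2000,
                                     scans_per_patient = 1,
                                     prevalence = 0.625, seed = 11))
  se2 <- sqrt(0.625 * 0.375 / 2000)
  expect_lt(abs(mean(co2$outcome == "malignant") - 0.625), 3 * se2)

  co3 <- simulate_cohort(cohort_spec(n_patients = 300, seed = 12))
  lab <- tapply(co3$outcome, co3$patient_id,
                function(o) length(unique(o)))
  expect_true(all(lab == 1))  # one ground truth per patient
  expect_identical(simulate_cohort(cohort_spec(n_patients = 300, seed = 12)),
                   co3)
})

test_that("cohort effect sizes are recovered by a univariable fit", {
  spec <- cohort_spec(n_patients = 5000, scans_per_patient = 1,
                      covariate_effects = c(age = 0.05),
                      intercept = -0.05 * 69, seed = 21)
  co <- simulate_cohort(spec)
  fit <- stats::glm(I(outcome == "malignant") ~ age, binomial(), data = co)
  expect_lt(abs(coef(fit)[["age"]] - 0.05), 0.01)
})

test_that("unknown effect names are rejected listing valid names", {
  expect_error(cohort_spec(covariate_effects = c(shoe_size = 1)),
               "valid names.*age", perl = TRUE)
  expect_error(cohort_spec(prevalence = 0), "strictly between")
})

test_that("cohort CSV round trip preserves the table", {
  co <- simulate_cohort(cohort_spec(n_patients = 40, seed = 2))
  tmp <- tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$scan_id, co$scan_id)
  expect_equal(back$nodule_size_mm, co$nodule_size_mm)
  expect_equal(back$outcome, co$outcome)
})
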