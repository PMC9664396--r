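# Covariate schema shared by the cohort CSV, the clinical risk calculators
# and the decision-support tool. One row per scan.
cohort_columns <- function() {
  c("patient_id", "scan_id", "timepoint", "age", "sex", "nodule_size_mm",
    "density", "spiculation", "upper_lobe", "nodule_count", "lung_disease",
    "family_history_lung_ca", "previous_lung_ca",
    "previous_extrathoracic_ca", "smoking", "pet_avidity", "outcome")
}

cohort_levels <- function() {
  list(sex = c("male", "female"),
       density = c("solid", "subsolid", "GGO"),
       smoking = c("never", "ex_current", "unknown"),
       pet_avidity = c("absent", "faint", "moderate", "intense", "missing"),
       timepoint = c("baseline", "interim", "final"),
       outcome = c("benign", "malignant", "unknown"))
}

# Covariates that may carry log-odds effects in the generative model.
# Categoricals enter through indicator terms; pet_score is the ordinal
# 0..3 coding of avidity (missing treated as absent).
effect_covariates <- function() {
  c("age", "nodule_size_mm", "spiculation", "upper_lobe", "nodule_count",
    "lung_disease", "family_history_lung_ca", "previous_lung_ca",
    "previous_extrathoracic_ca", "density_subsolid", "density_GGO",
    "smoking_ex_current", "sex_female", "pet_score")
}

#' Specify a simulated patient cohort
#'
#' The generative model emulates the covariate mix of a multi-centre
#' incidental large-nodule (15-30 mm) population: each patient receives
#' covariates drawn from documented marginals (age ~ N(69.1, 10.2) truncated
#' above 18; nodule size ~ N(20.5, 4.7) truncated to 15-30 mm; density
#' solid/subsolid/GGO = 70.6/22.8/6.6%; spiculation 23.9%; male 49%;
#' smoking never/ex-current/unknown = 13.8/69.7/16.5%; PET avidity
#' absent/faint/moderate/intense/missing = 6.3/17.8/24.9/18.5/32.5%; lung
#' disease 56.0%; previous lung cancer 3.8%; family history 1.2%; previous
#' extrathoracic cancer 22.8%), and a malignancy label drawn once per
#' patient from `logistic(intercept + sum(effect * covariate))`. Every scan
#' of a patient carries the patient's label: the diagnosis at the final
#' scan defines the ground truth for all earlier scans.
#'
#' @param n_patients Number of patients.
#' @param scans_per_patient Maximum scans per patient (1-3: baseline,
#'   interim, final); the per-patient count is drawn with probabilities
#'   0.50/0.32/0.18 (mean 1.68 scans/patient).
#' @param prevalence Target malignancy fraction in (0,1); sets the
#'   intercept to `qlogis(prevalence)` when `intercept` is `NULL`.
#' @param covariate_effects Named numeric vector of log-odds coefficients;
#'   names must come from the documented effect set (see errors).
#' @param intercept Optional explicit intercept (log-odds).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 500L,
                        scans_per_patient = 3L,
                        prevalence = 0.625,
                        covariate_effects = c(),
                        intercept = NULL,
                        seed = 1L) {
  stopifnot(n_patients >= 1, scans_per_patient >= 1, scans_per_patient <= 3)
  if (!is_scalar_number(prevalence) || prevalence <= 0 || prevalence >= 1)
    stopf("prevalence must lie strictly between 0 and 1")
  if (length(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), effect_covariates())
    if (length(bad))
      stopf("unknown covariate(s) in effects map: %s; valid names are: %s",
            paste(bad, collapse = ", "),
            paste(effect_covariates(), collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients),
                 scans_per_patient = as.integer(scans_per_patient),
                 prevalence = prevalence,
                 covariate_effects = covariate_effects,
                 intercept = if (is.null(intercept)) stats::qlogis(prevalence)
                             else intercept,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a scan-level cohort table
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per scan in the cohort CSV schema
#'   (see [read_cohort()]), deterministic given the spec's seed.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' table(co$outcome[co$timepoint == "baseline"])
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lv <- cohort_levels()
  with_seed(spec$seed, {
    n <- spec$n_patients
    age <- pmax(18.5, stats::rnorm(n, 69.1, 10.2))
    sex <- sample(lv$sex, n, TRUE, prob = c(0.49, 0.51))
    size <- pmin(30, pmax(15, stats::rnorm(n, 20.5, 4.7)))
    density <- sample(lv$density, n, TRUE, prob = c(0.706, 0.228, 0.066))
    spic <- stats::runif(n) < 0.239
    upper <- stats::runif(n) < 0.5
    count <- sample(1:4, n, TRUE, prob = c(0.70, 0.20, 0.07, 0.03))
    lungdis <- stats::runif(n) < 0.560
    fh <- stats::runif(n) < 0.012
    prevlung <- stats::runif(n) < 0.038
    prevextra <- stats::runif(n) < 0.228
    smoking <- sample(lv$smoking, n, TRUE, prob = c(0.138, 0.697, 0.165))
    pet <- sample(lv$pet_avidity, n, TRUE,
                  prob = c(0.063, 0.178, 0.249, 0.185, 0.325))
    pet_score <- match(pet, c("absent", "faint", "moderate", "intense")) - 1
    pet_score[is.na(pet_score)] <- 0   # missing treated as absent

    design <- cbind(age = age,
                    nodule_size_mm = size,
                    spiculation = as.numeric(spic),
                    upper_lobe = as.numeric(upper),
                    nodule_count = count,
                    lung_disease = as.numeric(lungdis),
                    family_history_lung_ca = as.numeric(fh),
                    previous_lung_ca = as.numeric(prevlung),
                    previous_extrathoracic_ca = as.numeric(prevextra),
                    density_subsolid = as.numeric(density == "subsolid"),
                    density_GGO = as.numeric(density == "GGO"),
                    smoking_ex_current = as.numeric(smoking == "ex_current"),
                    sex_female = as.numeric(sex == "female"),
                    pet_score = pet_score)
    eta <- rep(spec$intercept, n)
    if (length(spec$covariate_effects))
      eta <- eta + drop(design[, names(spec$covariate_effects), drop = FALSE] %*%
                          spec$covariate_effects)
    malignant <- stats::runif(n) < stats::plogis(eta)

    nscans <- if (spec$scans_per_patient == 1L) rep(1L, n) else
      sample(seq_len(spec$scans_per_patient), n, TRUE,
             prob = c(0.50, 0.32, 0.18)[seq_len(spec$scans_per_patient)])
    idx <- rep(seq_len(n), nscans)
    scan_no <- unlist(lapply(nscans, seq_len), use.names = FALSE)
    tp <- ifelse(scan_no == 1L, "baseline",
                 ifelse(scan_no == nscans[idx], "final", "interim"))
    data.frame(
      patient_id = sprintf("P%04d", idx),
      scan_id = sprintf("P%04d_S%d", idx, scan_no),
      timepoint = tp,
      age = round(age[idx], 1),
      sex = sex[idx],
      nodule_size_mm = round(size[idx], 1),
      density = density[idx],
      spiculation = spic[idx],
      upper_lobe = upper[idx],
      nodule_count = count[idx],
      lung_disease = lungdis[idx],
      family_history_lung_ca = fh[idx],
      previous_lung_ca = prevlung[idx],
      previous_extrathoracic_ca = prevextra[idx],
      smoking = smoking[idx],
      pet_avidity = pet[idx],
      outcome = ifelse(malignant[idx], "malignant", "benign"),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a feature matrix with a sparse logistic signal
#'
#' Generates `n` observations of `p` standard-normal features, the first
#' `length(beta)` of which drive a binary outcome through
#' `logistic(intercept + X beta)`. Used to exercise the screening/LASSO
#' development workflow with a known active set.
#'
#' @param n,p Observations and features.
#' @param beta Coefficients of the informative leading features.
#' @param intercept Log-odds intercept.
#' @param seed Integer RNG seed.
#' @return List with `X` (matrix, columns `feat_001`...) and `y` (0/1).
#' @export
simulate_features <- function(n, p, beta = c(1, -1), intercept = 0,
                              seed = 1L) {
  stopifnot(p >= length(beta))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("feat_%03d", seq_len(p))))
    eta <- intercept + drop(X[, seq_along(beta), drop = FALSE] %*% beta)
    y <- as.integer(stats::runif(n) < stats::plogis(eta))
    list(X = X, y = y)
  })
}

#' Read and write cohort tables
#'
#' The cohort CSV has one row per scan with the fixed column set
#' `patient_id, scan_id, timepoint, age, sex, nodule_size_mm, density,
#' spiculation, upper_lobe, nodule_count, lung_disease,
#' family_history_lung_ca, previous_lung_ca, previous_extrathoracic_ca,
#' smoking, pet_avidity, outcome`. `read_cohort()` validates column
#' presence and categorical levels, and warns for nodule sizes outside the
#' 15-30 mm study range (allowed, flagged as out-of-cohort).
#'
#' @param path CSV file path.
#' @return `read_cohort()`: validated data.frame; `write_cohort()`: the
#'   path, invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols))
    stopf("cohort table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  lv <- cohort_levels()
  for (col in names(lv)) {
    bad <- setdiff(unique(df[[col]]), lv[[col]])
    if (length(bad))
      stopf("invalid %s value(s): %s (allowed: %s)", col,
            paste(bad, collapse = ", "), paste(lv[[col]], collapse = ", "))
  }
  for (col in c("spiculation", "upper_lobe", "lung_disease",
                "family_history_lung_ca", "previous_lung_ca",
                "previous_extrathoracic_ca"))
    df[[col]] <- as.logical(df[[col]])
  if (any(df$age <= 18)) stopf("age must exceed 18 (study inclusion)")
  n_out <- sum(df$nodule_size_mm < 15 | df$nodule_size_mm > 30)
  if (n_out)
    warnf("%d scan(s) have nodule sizes outside the 15-30 mm cohort range",
          n_out)
  df
}
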