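# Cached coefficient tables, read once per session from the shipped
# constants file (inst/extdata/clinical_model_coefficients.csv), which is
# the single source of truth and carries a line-by-line citation column.
.clinical_env <- new.env(parent = emptyenv())

clinical_coefficients <- function(model = c("brock", "herder")) {
  model <- match.arg(model)
  if (is.null(.clinical_env$coef)) {
    path <- system.file("extdata", "clinical_model_coefficients.csv",
                        package = "lnrpv", mustWork = TRUE)
    .clinical_env$coef <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  tab <- .clinical_env$coef[.clinical_env$coef$model == model, ]
  stats::setNames(tab$coefficient, tab$term)
}

clinical_centering <- function(model, term) {
  path_tab <- .clinical_env$coef
  path_tab$centering[path_tab$model == model & path_tab$term == term]
}

require_fields <- function(rec, fields, fn) {
  rec <- as.list(rec)
  missing_f <- fields[!vapply(fields, function(f)
    !is.null(rec[[f]]) && !is.na(rec[[f]]), logical(1))]
  if (length(missing_f))
    stopf("%s: missing required covariate(s): %s", fn,
          paste(missing_f, collapse = ", "))
  rec
}

#' Brock malignancy probability (full model with spiculation)
#'
#' Logistic malignancy probability for a screening-detected nodule from
#' the Brock (PanCan) full model with spiculation, the variant the British
#' Thoracic Society pathway recommends; a probability of at least 10%
#' triggers further work-up. Coefficients are transcribed verbatim into
#' the shipped constants table (`clinical_model_coefficients.csv`) with a
#' citation per line. The cohort schema's `lung_disease` field maps to the
#' model's emphysema covariate (closest recorded field; documented
#' approximation).
#'
#' @param rec A clinical record: named list or one-row data.frame with
#'   `age`, `sex` ("male"/"female"), `nodule_size_mm`, `density` ("solid",
#'   "subsolid", "GGO"), `spiculation`, `upper_lobe`, `nodule_count`,
#'   `lung_disease`, `family_history_lung_ca`.
#' @return Probability of malignancy in percent (0-100).
#' @examples
#' brock_probability(list(age = 50, sex = "female", nodule_size_mm = 15,
#'   density = "solid", spiculation = FALSE, upper_lobe = FALSE,
#'   nodule_count = 1, lung_disease = FALSE,
#'   family_history_lung_ca = FALSE))  # ~10.3%: meets the 10% threshold
#' @export
brock_probability <- function(rec) {
  rec <- require_fields(rec, c("age", "sex", "nodule_size_mm", "density",
                               "spiculation", "upper_lobe", "nodule_count",
                               "lung_disease", "family_history_lung_ca"),
                        "brock_probability")
  b <- clinical_coefficients("brock")
  eta <- b[["intercept"]] +
    b[["age_per_year"]] * (rec$age - 62) +
    b[["sex_female"]] * (rec$sex == "female") +
    b[["family_history"]] * isTRUE(as.logical(rec$family_history_lung_ca)) +
    b[["emphysema"]] * isTRUE(as.logical(rec$lung_disease)) +
    b[["size_transform"]] *
      ((rec$nodule_size_mm / 10)^(-0.5) - 1.58113883) +
    b[["density_nonsolid"]] * (rec$density == "GGO") +
    b[["density_partsolid"]] * (rec$density == "subsolid") +
    b[["upper_lobe"]] * isTRUE(as.logical(rec$upper_lobe)) +
    b[["nodule_count_per_nodule"]] * (rec$nodule_count - 4) +
    b[["spiculation"]] * isTRUE(as.logical(rec$spiculation))
  100 * stats::plogis(unname(eta))
}

#' Herder malignancy probability (PET-adjusted model)
#'
#' Logistic malignancy probability from the Herder model: the Mayo-style
#' clinical covariates plus ordered categorical FDG-PET avidity
#' (absent/faint/moderate/intense). Records with `pet_avidity = "missing"`
#' must first pass through [impute_pet()] (the pipeline's convention is
#' that missing PET is treated as PET-negative).
#'
#' @param rec Named list or one-row data.frame with `age`, `smoking`
#'   ("never"/"ex_current"/"unknown"; unknown counts as never for the
#'   smoker indicator), `previous_extrathoracic_ca`, `nodule_size_mm`,
#'   `spiculation`, `upper_lobe`, `pet_avidity` ("absent", "faint",
#'   "moderate", "intense").
#' @return Probability of malignancy in percent (0-100).
#' @export
herder_probability <- function(rec) {
  rec <- require_fields(rec, c("age", "smoking", "previous_extrathoracic_ca",
                               "nodule_size_mm", "spiculation", "upper_lobe",
                               "pet_avidity"), "herder_probability")
  if (rec$pet_avidity == "missing")
    stopf("herder_probability: pet_avidity is missing; apply impute_pet() first")
  h <- clinical_coefficients("herder")
  pet_term <- switch(rec$pet_avidity,
                     absent = h[["pet_absent"]],
                     faint = h[["pet_faint"]],
                     moderate = h[["pet_moderate"]],
                     intense = h[["pet_intense"]],
                     stopf("herder_probability: unknown pet_avidity '%s'",
                           rec$pet_avidity))
  eta <- h[["intercept"]] +
    h[["age_per_year"]] * rec$age +
    h[["smoker_ever"]] * (rec$smoking == "ex_current") +
    h[["extrathoracic_cancer"]] *
      isTRUE(as.logical(rec$previous_extrathoracic_ca)) +
    h[["diameter_per_mm"]] * rec$nodule_size_mm +
    h[["spiculation"]] * isTRUE(as.logical(rec$spiculation)) +
    h[["upper_lobe"]] * isTRUE(as.logical(rec$upper_lobe)) +
    pet_term
  100 * stats::plogis(unname(eta))
}

#' Impute missing PET avidity as PET-negative
#'
#' Records with no recorded PET study are taken to be PET negative:
#' `pet_avidity = "missing"` becomes `"absent"` and the record is flagged
#' with `pet_imputed = TRUE`. All other fields are unchanged and the
#' operation is idempotent.
#'
#' @param rec Named list or one-row data.frame with `pet_avidity`.
#' @return The record with `pet_avidity` imputed and a `pet_imputed` flag.
#' @export
impute_pet <- function(rec) {
  rec <- as.list(rec)
  if (is.null(rec$pet_imputed)) rec$pet_imputed <- FALSE
  if (!is.null(rec$pet_avidity) && !is.na(rec$pet_avidity) &&
      rec$pet_avidity == "missing") {
    rec$pet_avidity <- "absent"
    rec$pet_imputed <- TRUE
  }
  rec
}

#' Brock and Herder scores for a whole cohort
#'
#' Applies [impute_pet()], [brock_probability()] and
#' [herder_probability()] row-wise over a cohort table.
#'
#' @param cohort Cohort data.frame in the schema of [read_cohort()].
#' @return The cohort with `brock_pct`, `herder_pct`,
#'   `herder_pet_category_used` and `pet_imputed` columns appended.
#' @export
score_cohort_clinical <- function(cohort) {
  n <- nrow(cohort)
  brock <- herder <- numeric(n)
  used <- character(n)
  imputed <- logical(n)
  for (i in seq_len(n)) {
    rec <- impute_pet(as.list(cohort[i, ]))
    brock[i] <- brock_probability(rec)
    herder[i] <- herder_probability(rec)
    used[i] <- rec$pet_avidity
    imputed[i] <- rec$pet_imputed
  }
  cohort$brock_pct <- brock
  cohort$herder_pct <- herder
  cohort$herder_pet_category_used <- used
  cohort$pet_imputed <- imputed
  cohort
}
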