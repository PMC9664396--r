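herder_band <- function(herder_pct) {
  if (any(herder_pct < 0 | herder_pct > 100))
    stopf("herder percentage out of [0, 100]")
  # band edges: 10 and 70 both belong to the intermediate band
  ifelse(herder_pct < 10, "<10",
         ifelse(herder_pct <= 70, "10-70", ">70"))
}

#' Decision-support recommendation for one scan
#'
#' Integrates the Herder probability band with the LN-RPV risk group: a
#' Herder score below 10% routes to surveillance, above 70% to the
#' high-risk pathway, and within the intermediate 10-70% band a high
#' LN-RPV risk group upgrades the nodule to early intervention while a
#' low risk group keeps standard work-up. The radiomics score only ever
#' prompts *earlier* intervention - it never downgrades a recommendation.
#' The rule is modelled for solid nodules at baseline; non-solid input
#' returns standard work-up with a scope warning.
#'
#' @param herder_pct Herder probability in percent, 0-100.
#' @param rpv_risk `"low"` or `"high"` LN-RPV risk group.
#' @param density Nodule density (`"solid"` in scope).
#' @param timepoint Scan timepoint (informational).
#' @return A `decision_outcome` list: `herder_pct`, `herder_band`,
#'   `rpv_risk`, `recommendation` (one of `surveillance_pathway`,
#'   `standard_workup`, `upgrade_early_intervention`,
#'   `high_risk_pathway`), `upgraded`.
#' @examples
#' recommend(50, "high")$recommendation  # upgrade_early_intervention
#' @export
recommend <- function(herder_pct, rpv_risk = c("low", "high"),
                      density = "solid", timepoint = "baseline") {
  rpv_risk <- match.arg(rpv_risk)
  band <- herder_band(herder_pct)
  if (density != "solid") {
    warnf("decision rule is modelled for solid nodules; density '%s' routed to standard work-up",
          density)
    rec <- "standard_workup"
    band_out <- band
    upg <- FALSE
  } else {
    rec <- switch(band,
                  "<10" = "surveillance_pathway",
                  "10-70" = if (rpv_risk == "high")
                    "upgrade_early_intervention" else "standard_workup",
                  ">70" = "high_risk_pathway")
    band_out <- band
    upg <- band == "10-70" && rpv_risk == "high"
  }
  structure(list(herder_pct = herder_pct, herder_band = band_out,
                 rpv_risk = rpv_risk, recommendation = rec,
                 upgraded = upg, density = density, timepoint = timepoint),
            class = "decision_outcome")
}

#' Cross-tabulate LN-RPV risk against Herder bands
#'
#' Builds the decision-support cross-tabulation for scans with Herder
#' scores of at least 10%: counts per (Herder band) x (LN-RPV risk) cell,
#' split into actual benign / malignant. Rows with unknown outcome are
#' excluded with a warning.
#'
#' @param outcomes data.frame with columns `herder_pct`, `rpv_risk`
#'   (`"low"`/`"high"`) and `outcome` (`"benign"`/`"malignant"`/
#'   `"unknown"`).
#' @return A `cross_tab` list: `counts` (3-D array band x risk x outcome)
#'   and `table` (data.frame rendering with `benign`, `malignant`,
#'   `total` per cell).
#' @export
cross_tabulate <- function(outcomes) {
  need <- c("herder_pct", "rpv_risk", "outcome")
  miss <- setdiff(need, names(outcomes))
  if (length(miss))
    stopf("outcomes table lacks column(s): %s", paste(miss, collapse = ", "))
  unk <- outcomes$outcome == "unknown" | is.na(outcomes$outcome)
  if (any(unk)) {
    warnf("excluding %d row(s) with unknown outcome", sum(unk))
    outcomes <- outcomes[!unk, , drop = FALSE]
  }
  band <- herder_band(outcomes$herder_pct)
  keep <- band != "<10"
  outcomes <- outcomes[keep, , drop = FALSE]
  band <- factor(band[keep], levels = c("10-70", ">70"))
  risk <- factor(outcomes$rpv_risk, levels = c("low", "high"))
  oc <- factor(outcomes$outcome, levels = c("benign", "malignant"))
  counts <- table(band = band, risk = risk, outcome = oc)
  tab <- as.data.frame(expand.grid(band = levels(band),
                                   risk = levels(risk),
                                   stringsAsFactors = FALSE))
  tab$benign <- mapply(function(b, r) counts[b, r, "benign"],
                       tab$band, tab$risk)
  tab$malignant <- mapply(function(b, r) counts[b, r, "malignant"],
                          tab$band, tab$risk)
  tab$total <- tab$benign + tab$malignant
  structure(list(counts = counts, table = tab), class = "cross_tab")
}

#' Upgrade summary for the intermediate Herder band
#'
#' From the 10-70% band of a [cross_tabulate()] result: how many
#' malignant nodules sit in the band, how many of them the tool upgrades
#' (high LN-RPV), the upgraded percentage, and the band's malignancy
#' rate. Percentages are rounded to whole numbers for reporting.
#'
#' @param tab A `cross_tab`.
#' @return List: `n_band` (all nodules in the band),
#'   `n_malignant_in_band`, `n_upgraded_malignant`, `pct_upgraded`
#'   (`NA` when the band has no malignant nodules), `band_malignancy_pct`.
#' @export
upgrade_summary <- function(tab) {
  stopifnot(inherits(tab, "cross_tab"))
  cnt <- tab$counts
  n_mal <- sum(cnt["10-70", , "malignant"])
  n_band <- sum(cnt["10-70", , ])
  n_up <- cnt["10-70", "high", "malignant"]
  list(n_band = n_band,
       n_malignant_in_band = n_mal,
       n_upgraded_malignant = as.integer(n_up),
       pct_upgraded = if (n_mal > 0) round(100 * n_up / n_mal) else NA_real_,
       band_malignancy_pct = if (n_band > 0) round(100 * n_mal / n_band)
                             else NA_real_)
}

#' Score a cohort end to end and apply the decision rule
#'
#' Convenience wrapper: clinical scores via [score_cohort_clinical()],
#' LN-RPV risk groups from supplied scores and clusters, and the
#' [recommend()] rule per scan.
#'
#' @param cohort Cohort data.frame (schema of [read_cohort()]).
#' @param rpv_scores Numeric LN-RPV per row of `cohort`.
#' @param clusters [fit_risk_clusters()] result.
#' @return The cohort with `brock_pct`, `herder_pct`, `rpv`, `rpv_risk`,
#'   `herder_band`, `recommendation` and `upgraded` columns.
#' @export
decide_cohort <- function(cohort, rpv_scores, clusters) {
  stopifnot(nrow(cohort) == length(rpv_scores))
  sc <- score_cohort_clinical(cohort)
  sc$rpv <- rpv_scores
  sc$rpv_risk <- assign_risk(rpv_scores, clusters)
  recs <- mapply(function(h, r, d, t) {
    o <- suppressWarnings(recommend(h, r, d, t))
    c(o$herder_band, o$recommendation, o$upgraded)
  }, sc$herder_pct, sc$rpv_risk, sc$density, sc$timepoint)
  sc$herder_band <- recs[1, ]
  sc$recommendation <- recs[2, ]
  sc$upgraded <- as.logical(recs[3, ])
  sc
}
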