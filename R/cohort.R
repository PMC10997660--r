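# Assembly of the analysis dataset from raw claims tables: exposures,
# comorbidities, outcomes, mediators.

#' Build the cohort analysis frame from claims tables
#'
#' Runs the full cohort construction once for all drugs: combination
#' splitting and chronic-exposure coding, the >= `min_exposed` medication
#' filter, comorbidity detection under the chosen timeframe, OS and DFS
#' outcome construction, and the mediators from the tumor table. Per-drug
#' analysis tables (exposure, adjusted covariate set, outcomes) are then cut
#' from this frame with [analysis_table_for_drug()].
#'
#' @param dataset a `claims_dataset`.
#' @param rules an [exposure_rules()].
#' @param code_map named code -> condition map for comorbidity detection.
#' @param timeframe comorbidity timeframe (see [detect_comorbidities()]).
#' @param min_exposed minimum chronically exposed patients per screened drug.
#' @param cutoff_os,cutoff_dfs administrative cutoffs for the outcomes.
#' @return list of class `cohort_frame`: `base` (per-patient data.frame with
#'   demographics, comorbidity indicators, outcomes, mediators and
#'   `med_count`), `flags` (patient x drug chronic-exposure matrix),
#'   `eligible` (screened drug codes), `exposed_counts`.
#' @export
build_cohort_frame <- function(dataset, rules = exposure_rules(),
                               code_map = default_code_map(),
                               timeframe = "primary",
                               min_exposed = 300,
                               cutoff_os = as.Date("2019-03-01"),
                               cutoff_dfs = as.Date("2018-12-30")) {
  pts <- dataset$patients
  surgery_gap <- dataset$config$surgery_gap_days %||% 30
  surgery_date <- pts$index_date + surgery_gap

  expo <- build_exposure_table(dataset, rules)
  eligible <- filter_medications(expo$exposed_counts, rules, min_exposed)

  com <- .comorbidity_matrix(dataset$code_events, pts, surgery_date,
                             code_map, timeframe)
  colnames(com) <- paste0("comorb_", colnames(com))

  os <- compute_os(surgery_date, pts$death_date, cutoff_os)
  dfs <- .derive_dfs_bulk(dataset$care_events, pts, surgery_date, cutoff_dfs)

  tum <- dataset$tumors[match(pts$patient_id, dataset$tumors$patient_id), ]
  base <- data.frame(
    patient_id = pts$patient_id,
    age = pts$age, deprivation = pts$deprivation,
    gp_visits = pts$gp_visits, gyn_visits = pts$gyn_visits,
    screening = as.numeric(pts$screening),
    com * 1,
    med_count = expo$med_count,
    subtype = tum$subtype, node = as.integer(tum$node_positive),
    os, dfs,
    stringsAsFactors = FALSE)
  structure(list(base = base, flags = expo$flags, eligible = eligible,
                 exposed_counts = expo$exposed_counts),
            class = "cohort_frame")
}

#' Per-drug analysis table
#'
#' Cuts the analysis table for one screened drug from a [build_cohort_frame()]:
#' the chronic-exposure flag for the drug, the pre-exposure adjustment set
#' (demographics, care utilization, screening, comorbidity indicators, the
#' medication count excluding the index drug, and chronic co-exposure flags
#' for the `top_k` most prevalent other drugs), the outcomes and mediators.
#'
#' @param frame a `cohort_frame`.
#' @param drug ATC code of the index drug.
#' @param top_k number of co-exposure indicator drugs (default 20).
#' @return data.frame with attribute `"covariates"` naming the adjustment
#'   set.
#' @export
analysis_table_for_drug <- function(frame, drug, top_k = 20) {
  if (!drug %in% colnames(frame$flags))
    stop_pharmscreen("no exposure information for drug ", drug)
  base <- frame$base
  expo <- as.integer(frame$flags[, drug])
  others <- setdiff(colnames(frame$flags), drug)
  counts <- frame$exposed_counts[others]
  top <- names(sort(counts, decreasing = TRUE))[seq_len(min(top_k,
                                                            length(others)))]
  co <- frame$flags[, top, drop = FALSE] * 1
  colnames(co) <- paste0("coexp_", top)
  out <- cbind(base, exposure = expo,
               med_count_excl = base$med_count - expo)
  out$med_count <- NULL
  if (ncol(co)) out <- cbind(out, co)
  covs <- c("age", "deprivation", "gp_visits", "gyn_visits", "screening",
            grep("^comorb_", names(base), value = TRUE), "med_count_excl",
            colnames(co))
  attr(out, "covariates") <- covs
  out
}
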