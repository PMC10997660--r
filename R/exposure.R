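# Chronic-exposure phenotyping from dispensing streams: combination
# splitting, per-drug covered-days coding, medication filtering.

#' Split combination-product dispensings into their components
#'
#' Each dispensing whose ATC code appears in the combination map is replaced
#' by one dispensing per component with identical date and quantities;
#' other rows pass through unchanged.
#'
#' @param dispensings dispensing table (`patient_id`, `date`, `atc_code`,
#'   `packs`, `units_per_pack`, `daily_dose`).
#' @param combination_map named list, combination ATC -> character vector of
#'   component ATC codes.
#' @return dispensing table with combinations expanded.
#' @export
split_combinations <- function(dispensings, combination_map = list()) {
  if (length(combination_map) == 0 || nrow(dispensings) == 0)
    return(dispensings)
  if (any(lengths(combination_map) == 0))
    stop_pharmscreen("combination_map components must be non-empty")
  hit <- dispensings$atc_code %in% names(combination_map)
  if (!any(hit)) return(dispensings)
  plain <- dispensings[!hit, , drop = FALSE]
  combo <- dispensings[hit, , drop = FALSE]
  comp <- combination_map[combo$atc_code]
  k <- lengths(comp)
  expanded <- combo[rep(seq_len(nrow(combo)), k), , drop = FALSE]
  expanded$atc_code <- unlist(comp, use.names = FALSE)
  out <- rbind(plain, expanded)
  rownames(out) <- NULL
  out
}

# Per-row covered days with dose rules; drops invalid rows with a warning.
.covered_days_rows <- function(disp, rules) {
  bad <- disp$packs <= 0 | disp$units_per_pack <= 0
  if (any(bad)) {
    warning(sum(bad), " dispensing(s) with non-positive packs or units dropped",
            call. = FALSE)
    disp <- disp[!bad, , drop = FALSE]
  }
  upd <- rep(1, nrow(disp))
  if (length(rules$dose_rules)) {
    hit <- match(disp$atc_code, names(rules$dose_rules))
    upd[!is.na(hit)] <- unlist(rules$dose_rules)[hit[!is.na(hit)]]
  }
  disp$covered <- disp$packs * disp$units_per_pack / upd
  disp
}

#' Code chronic exposure to one drug for one patient
#'
#' Applies the exposure rule: sum the covered days (packs x units per pack /
#' units per day) of all dispensings of the drug in the window
#' `[index - window_days, index - 1]`, cap at the window length, and flag
#' "chronic" when the total reaches `min_covered_days`.
#'
#' @param dispensings one patient's dispensing table.
#' @param index_date diagnosis (index) date.
#' @param drug ATC code of the drug being coded.
#' @param rules an [exposure_rules()] object.
#' @return logical flag: chronically exposed or not.
#' @export
code_chronic_exposure <- function(dispensings, index_date, drug,
                                  rules = exposure_rules()) {
  d <- dispensings[dispensings$atc_code == drug, , drop = FALSE]
  if (nrow(d) == 0) return(FALSE)
  rel <- as.numeric(as.Date(d$date) - as.Date(index_date))
  d <- d[rel >= -rules$window_days & rel <= -1, , drop = FALSE]
  if (nrow(d) == 0) return(FALSE)
  d <- .covered_days_rows(d, rules)
  min(sum(d$covered), rules$window_days) >= rules$min_covered_days
}

#' Chronic-exposure table for every patient and drug
#'
#' Vectorized application of [code_chronic_exposure()] across the whole
#' dispensing table (after combination splitting and removal of excluded ATC
#' prefixes), plus the per-patient medication count.
#'
#' @param dataset a `claims_dataset` (or any list with `dispensings` and
#'   `patients` tables).
#' @param rules an [exposure_rules()].
#' @return list with `flags` (logical patient x drug matrix, patients as
#'   rows in `patients` table order), `med_count` (per-patient number of
#'   chronic drugs), and `exposed_counts` (named per-drug exposed counts).
#' @export
build_exposure_table <- function(dataset, rules = exposure_rules()) {
  pts <- dataset$patients
  disp <- split_combinations(dataset$dispensings, rules$combination_map)
  if (nrow(disp)) {
    excl <- rep(FALSE, nrow(disp))
    for (pre in rules$exclusions)
      excl <- excl | startsWith(disp$atc_code, pre)
    disp <- disp[!excl, , drop = FALSE]
  }
  drugs <- sort(unique(disp$atc_code))
  flags <- matrix(FALSE, nrow(pts), length(drugs),
                  dimnames = list(pts$patient_id, drugs))
  if (nrow(disp)) {
    idx <- pts$index_date[match(disp$patient_id, pts$patient_id)]
    rel <- as.numeric(as.Date(disp$date) - idx)
    disp <- disp[rel >= -rules$window_days & rel <= -1, , drop = FALSE]
    if (nrow(disp)) {
      disp <- .covered_days_rows(disp, rules)
      key <- paste(disp$patient_id, disp$atc_code, sep = "\r")
      cov <- rowsum(disp$covered, key)
      covered <- pmin(cov[, 1], rules$window_days)
      chronic <- covered >= rules$min_covered_days
      parts <- strsplit(rownames(cov), "\r", fixed = TRUE)
      pid <- vapply(parts, `[`, character(1), 1)
      atc <- vapply(parts, `[`, character(1), 2)
      flags[cbind(match(pid, pts$patient_id), match(atc, drugs))] <- chronic
    }
  }
  list(flags = flags,
       med_count = rowSums(flags),
       exposed_counts = colSums(flags))
}

#' Filter screened medications by exposed-patient count and exclusions
#'
#' Keeps drugs with at least `min_exposed` chronically exposed patients,
#' drops excluded ATC prefixes, and returns the eligible codes sorted.
#'
#' @param exposed_counts named integer vector, drug -> number of chronically
#'   exposed patients.
#' @param rules an [exposure_rules()].
#' @param min_exposed minimum exposed-patient count (default 300).
#' @return sorted character vector of eligible ATC codes.
#' @export
filter_medications <- function(exposed_counts, rules = exposure_rules(),
                               min_exposed = 300) {
  if (any(exposed_counts < 0)) stop_pharmscreen("counts must be non-negative")
  drugs <- names(exposed_counts)[exposed_counts >= min_exposed]
  if (length(drugs)) {
    keep <- rep(TRUE, length(drugs))
    for (pre in rules$exclusions)
      keep <- keep & !startsWith(drugs, pre)
    drugs <- drugs[keep]
  }
  sort(drugs)
}
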