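# Comorbidity detection windows and the OS/DFS outcome constructions.

#' Detect comorbid conditions from coded events
#'
#' Maps diagnosis and procedure codes falling in condition-ascertainment
#' windows around diagnosis to comorbid conditions. Windows (in days):
#' \describe{
#'   \item{primary}{diagnosis codes in `[index - 365, index + 180]`,
#'     procedure codes in `[index - 365, index]`.}
#'   \item{sensitivity_a}{diagnosis codes in `[index - 365, surgery]`.}
#'   \item{sensitivity_b}{diagnosis codes in `[surgery - 365, surgery]`.}
#' }
#' Procedure codes use the primary window under every timeframe. Codes
#' missing from `code_map` are ignored.
#'
#' @param code_events one patient's coded events (`date`, `code`, `source`
#'   with source in diagnosis/procedure).
#' @param index_date diagnosis date.
#' @param surgery_date first breast surgery date.
#' @param code_map named character vector, code -> condition.
#' @param timeframe one of "primary", "sensitivity_a", "sensitivity_b".
#' @return sorted character vector of detected conditions.
#' @export
detect_comorbidities <- function(code_events, index_date, surgery_date,
                                 code_map = default_code_map(),
                                 timeframe = c("primary", "sensitivity_a",
                                               "sensitivity_b")) {
  timeframe <- match.arg(timeframe)
  if (nrow(code_events) == 0) return(character(0))
  index_date <- as.Date(index_date); surgery_date <- as.Date(surgery_date)
  d <- as.Date(code_events$date)
  win <- switch(timeframe,
    primary = c(index_date - 365, index_date + 180),
    sensitivity_a = c(index_date - 365, surgery_date),
    sensitivity_b = c(surgery_date - 365, surgery_date))
  is_dx <- code_events$source == "diagnosis"
  keep_dx <- is_dx & d >= win[1] & d <= win[2]
  keep_pr <- !is_dx & d >= index_date - 365 & d <= index_date
  codes <- code_events$code[keep_dx | keep_pr]
  sort(unique(unname(code_map[codes[codes %in% names(code_map)]])))
}

# Vectorized comorbidity indicator matrix (patients x conditions).
.comorbidity_matrix <- function(code_events, patients, surgery_date,
                                code_map = default_code_map(),
                                timeframe = "primary") {
  conds <- sort(unique(unname(code_map)))
  M <- matrix(FALSE, nrow(patients), length(conds),
              dimnames = list(patients$patient_id, conds))
  if (nrow(code_events) == 0 || length(conds) == 0) return(M)
  i <- match(code_events$patient_id, patients$patient_id)
  idx <- patients$index_date[i]
  surg <- surgery_date[i]
  d <- as.Date(code_events$date)
  lo <- switch(timeframe, primary = idx - 365, sensitivity_a = idx - 365,
               sensitivity_b = surg - 365)
  hi <- switch(timeframe, primary = idx + 180, sensitivity_a = surg,
               sensitivity_b = surg)
  is_dx <- code_events$source == "diagnosis"
  keep <- (is_dx & d >= lo & d <= hi) |
    (!is_dx & d >= idx - 365 & d <= idx)
  keep <- keep & code_events$code %in% names(code_map)
  if (any(keep))
    M[cbind(i[keep], match(unname(code_map[code_events$code[keep]]), conds))] <- TRUE
  M
}

#' Overall survival from surgery
#'
#' Time in months from the first breast surgery to death, censored at the
#' administrative cutoff; deaths after the cutoff are censored at the cutoff.
#'
#' @param surgery_date date(s) of first breast surgery.
#' @param death_date date(s) of death, `NA` when alive.
#' @param cutoff administrative cutoff date.
#' @return data.frame with `os_time` (months) and `os_event` (0/1).
#' @export
compute_os <- function(surgery_date, death_date,
                       cutoff = as.Date("2019-03-01")) {
  surgery_date <- as.Date(surgery_date)
  death_date <- as.Date(death_date)
  cutoff <- as.Date(cutoff)
  if (any(!is.na(death_date) & death_date < surgery_date))
    stop_pharmscreen("death before surgery")
  event <- !is.na(death_date) & death_date <= cutoff
  end <- as.Date(ifelse(event, death_date, cutoff), origin = "1970-01-01")
  data.frame(os_time = days_to_months(end - surgery_date),
             os_event = as.integer(event))
}

DFS_RESUMPTION_KINDS <- c("radiotherapy_start", "chemo_start", "targeted_start")

# Recurrence-proxy rules, in tie-break order. Returns a data.frame of
# qualifying (date, reason) candidates for one patient.
.dfs_candidates <- function(care_events, surgery_date, initial_treatment_end) {
  d <- as.Date(care_events$date)
  kind <- care_events$kind
  six_mo_tx <- as.Date(initial_treatment_end) + 183
  six_mo_surg <- as.Date(surgery_date) + 183
  out <- list()
  # (i) resumption of radio/chemo/targeted therapy >= 6 months after the end
  # of initial treatments
  i1 <- kind %in% DFS_RESUMPTION_KINDS & d >= six_mo_tx
  if (any(i1)) out$treatment_resumption <- min(d[i1])
  # (ii) breast surgery with an axillary procedure the same day, >= 6 months
  # after the end of initial treatments
  bs <- d[kind == "breast_surgery" & d >= six_mo_tx]
  ax <- d[kind == "axillary_procedure"]
  bs <- bs[bs %in% ax]
  if (length(bs)) out$surgery_with_axillary <- min(bs)
  # (iii) metastatic-only anti-cancer molecule >= 6 months after surgery
  i3 <- kind == "metastatic_drug" & d >= six_mo_surg
  if (any(i3)) out$metastatic_drug <- min(d[i3])
  # (iv) metastasis diagnosis code in a hospital stay >= 6 months after surgery
  i4 <- kind == "metastasis_code" & d >= six_mo_surg
  if (any(i4)) out$metastasis_code <- min(d[i4])
  out
}

#' Disease-free survival from surgery
#'
#' Time in months from the first breast surgery to the earliest of: a
#' qualifying recurrence proxy, death, or the DFS cutoff. Recurrence proxies
#' are (i) resumption of radiotherapy/chemotherapy/targeted therapy at least
#' six months after the end of the initial treatments, (ii) a breast surgery
#' with axillary procedure at least six months after the end of the initial
#' treatments, (iii) intake of a metastatic-setting-only anti-cancer molecule
#' at least six months after surgery, (iv) a metastasis diagnosis code at
#' least six months after surgery. Ties are broken in rule order. Second
#' primary cancers at other sites are never events.
#'
#' @param care_events one patient's care events (`date`, `kind`).
#' @param surgery_date first breast surgery date.
#' @param initial_treatment_end end date of the initial treatments (surgery
#'   date when no adjuvant treatment was given).
#' @param death_date date of death or `NA`.
#' @param cutoff administrative DFS cutoff date.
#' @return one-row data.frame: `dfs_time` (months), `dfs_event` (0/1),
#'   `recurrence_reason` (one of treatment_resumption,
#'   surgery_with_axillary, metastatic_drug, metastasis_code, death, none).
#' @export
derive_dfs <- function(care_events, surgery_date, initial_treatment_end,
                       death_date = NA, cutoff = as.Date("2018-12-30")) {
  surgery_date <- as.Date(surgery_date)
  initial_treatment_end <- as.Date(initial_treatment_end)
  if (initial_treatment_end < surgery_date)
    stop_pharmscreen("initial_treatment_end before surgery")
  death_date <- as.Date(death_date)
  cutoff <- as.Date(cutoff)
  cand <- .dfs_candidates(care_events, surgery_date, initial_treatment_end)
  rec_date <- if (length(cand))
    as.Date(unname(do.call(c, cand)[which.min(unlist(cand))])) else
    as.Date(NA)
  rec_reason <- if (length(cand)) names(cand)[which.min(unlist(cand))] else NA
  events <- c(recurrence = rec_date, death = unname(death_date))
  events <- events[!is.na(events) & events <= cutoff]
  if (length(events) == 0) {
    return(data.frame(dfs_time = days_to_months(cutoff - surgery_date),
                      dfs_event = 0L, recurrence_reason = "none",
                      stringsAsFactors = FALSE))
  }
  first <- which.min(events)  # ties: recurrence listed first wins
  reason <- if (names(events)[first] == "recurrence") rec_reason else "death"
  data.frame(dfs_time = days_to_months(events[first] - surgery_date),
             dfs_event = 1L, recurrence_reason = reason,
             stringsAsFactors = FALSE)
}

# Vectorized DFS over a whole cohort. `patients` must carry death_date;
# treatment end is the latest initial chemo/radiotherapy end within 12
# months of surgery (surgery date when none).
.derive_dfs_bulk <- function(care_events, patients, surgery_date,
                             cutoff = as.Date("2018-12-30")) {
  n <- nrow(patients)
  pid <- patients$patient_id
  ce_i <- match(care_events$patient_id, pid)
  d <- as.Date(care_events$date)
  kind <- care_events$kind
  surg_of <- surgery_date[ce_i]

  # initial treatment end: latest chemo/radiotherapy end within a year
  is_end <- kind %in% c("chemo_end", "radiotherapy_end") &
    d <= surg_of + 365 & d >= surg_of
  tx_end <- surgery_date
  if (any(is_end)) {
    mx <- tapply(as.numeric(d[is_end]), ce_i[is_end], max)
    tx_end[as.integer(names(mx))] <-
      pmax(tx_end[as.integer(names(mx))], as.Date(mx, origin = "1970-01-01"))
  }

  six_tx <- tx_end[ce_i] + 183
  six_surg <- surg_of + 183
  rule_rank <- rep(NA_integer_, length(kind))
  ok1 <- kind %in% DFS_RESUMPTION_KINDS & d >= six_tx
  ok3 <- kind == "metastatic_drug" & d >= six_surg
  ok4 <- kind == "metastasis_code" & d >= six_surg
  # rule ii needs same-day surgery+axillary pairs; match within patient
  ax_key <- paste(care_events$patient_id, d)[kind == "axillary_procedure"]
  ok2 <- kind == "breast_surgery" & d >= six_tx &
    paste(care_events$patient_id, d) %in% ax_key
  rule_rank[ok4] <- 4L; rule_rank[ok3] <- 3L; rule_rank[ok2] <- 2L
  rule_rank[ok1] <- 1L
  qual <- !is.na(rule_rank)

  rec_date <- as.Date(rep(NA, n))
  rec_rule <- rep(NA_integer_, n)
  if (any(qual)) {
    ord <- order(ce_i[qual], d[qual], rule_rank[qual])
    qi <- ce_i[qual][ord]; qd <- d[qual][ord]; qr <- rule_rank[qual][ord]
    first <- !duplicated(qi)
    rec_date[qi[first]] <- qd[first]
    rec_rule[qi[first]] <- qr[first]
  }

  reasons <- c("treatment_resumption", "surgery_with_axillary",
               "metastatic_drug", "metastasis_code")
  death <- as.Date(patients$death_date)
  rec_ok <- !is.na(rec_date) & rec_date <= cutoff
  death_ok <- !is.na(death) & death <= cutoff
  end <- rep(cutoff, n)
  event <- rec_ok | death_ok
  end[death_ok] <- death[death_ok]
  use_rec <- rec_ok & (!death_ok | rec_date <= end)
  end[use_rec] <- rec_date[use_rec]
  reason <- rep("none", n)
  reason[death_ok] <- "death"
  reason[use_rec] <- reasons[rec_rule[use_rec]]
  data.frame(dfs_time = days_to_months(end - surgery_date),
             dfs_event = as.integer(event),
             recurrence_reason = reason, stringsAsFactors = FALSE)
}
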