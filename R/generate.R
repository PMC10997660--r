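# Synthetic claims cohort generator: structural causal model with known
# ground truth, emitting SNDS-like tables.

# --- internal simulation kernels -------------------------------------------

# Truncated-normal ages via inverse-CDF so a single uniform draw per patient
# drives the value (keeps streams reproducible and cheap).
.sim_age <- function(n, cfg) {
  lo <- stats::pnorm(cfg$age_min, cfg$age_mean, cfg$age_sd)
  hi <- stats::pnorm(cfg$age_max, cfg$age_mean, cfg$age_sd)
  stats::qnorm(stats::runif(n, lo, hi), cfg$age_mean, cfg$age_sd)
}

.design_matrix <- function(age, deprivation, gp_visits, gyn_visits, screening,
                           comorbs, cfg) {
  X <- cbind(
    age_z = (age - cfg$age_mean) / cfg$age_sd,
    deprivation_c = (deprivation - 3) / 2,
    gp_visits_c = (gp_visits - 5) / 5,
    gyn_visits_c = gyn_visits - 0.7,
    screening = as.numeric(screening),
    comorb_cardiovascular = as.numeric(comorbs$cardiovascular),
    comorb_metabolic = as.numeric(comorbs$metabolic),
    comorb_psychiatric = as.numeric(comorbs$psychiatric)
  )
  X[, COVARIATE_NAMES, drop = FALSE]
}

.sim_covariates <- function(n, cfg) {
  age <- .sim_age(n, cfg)
  z_age <- (age - cfg$age_mean) / cfg$age_sd
  deprivation <- sample(1:5, n, replace = TRUE)
  gp_visits <- stats::rpois(n, exp(1.6 + 0.25 * z_age))
  gyn_visits <- stats::rpois(n, exp(-0.3 - 0.2 * z_age))
  screening <- stats::rbinom(n, 1, expit(-0.5)) == 1
  comorbs <- lapply(cfg$gamma, function(g) {
    stats::rbinom(n, 1, expit(g[1] + g[2] * z_age)) == 1
  })
  names(comorbs) <- names(cfg$gamma)
  X <- .design_matrix(age, deprivation, gp_visits, gyn_visits, screening,
                      comorbs, cfg)
  list(age = age, deprivation = deprivation, gp_visits = gp_visits,
       gyn_visits = gyn_visits, screening = screening, comorbs = comorbs,
       X = X)
}

.check_lp <- function(lp, what) {
  if (length(lp) && any(!is.finite(lp)))
    stop_pharmscreen("non-finite linear predictor in ", what,
                     "; rejecting config")
  lp
}

# Subtype probabilities (n x 4, luminal reference) under exposure level `a`
# (scalar or vector).
.subtype_probs <- function(a, X, cfg) {
  n <- nrow(X)
  eta <- matrix(0, n, 4)
  for (k in 2:4) {
    kap <- cfg$kappa_m1[SUBTYPE_LEVELS[k], ]
    eta[, k] <- .check_lp(kap["intercept"] + kap["exposure"] * a +
                            drop(X %*% kap[COVARIATE_NAMES]), "subtype model")
  }
  ex <- exp(eta)
  ex / rowSums(ex)
}

# Draw subtype (integer 1..4) from one uniform per patient: common random
# numbers across counterfactual exposure settings.
.sim_subtype <- function(a, X, cfg, u = stats::runif(nrow(X))) {
  if (nrow(X) == 0) return(integer(0))
  p <- .subtype_probs(a, X, cfg)
  c1 <- p[, 1]; c2 <- c1 + p[, 2]; c3 <- c2 + p[, 3]
  1L + (u > c1) + (u > c2) + (u > c3)
}

.node_prob <- function(a, X, m1, cfg) {
  kap <- cfg$kappa_m2
  sub_eff <- c(0, kap[SUBTYPE_LEVELS[-1]])[m1]
  expit(.check_lp(kap["intercept"] + kap["exposure"] * a + sub_eff +
                    drop(X %*% kap[COVARIATE_NAMES]), "nodal-status model"))
}

.sim_node <- function(a, X, m1, cfg, u = stats::runif(nrow(X))) {
  as.integer(u < .node_prob(a, X, m1, cfg))
}

# Weibull-PH event time: S(t) = exp(-rate * exp(eta) * t^shape), months.
.hazard_lp <- function(a, X, m1, m2, cfg, extra = 0) {
  sub_eff <- c(0, cfg$beta$subtype[SUBTYPE_LEVELS[-1]])[m1]
  .check_lp(cfg$beta$exposure * a + sub_eff + cfg$beta$node * m2 +
              drop(X %*% cfg$beta$covariates[COVARIATE_NAMES]) + extra,
            "hazard model")
}

.sim_event_time <- function(eta, cfg, u = stats::runif(length(eta))) {
  (-log(u) / (cfg$weibull_rate * exp(eta)))^(1 / cfg$weibull_shape)
}

# --- dispensing stream builders --------------------------------------------

.empty_dispensings <- function() {
  data.frame(patient_id = character(0), date = as.Date(character(0)),
              atc_code = character(0), packs = numeric(0),
              units_per_pack = numeric(0), daily_dose = numeric(0),
              stringsAsFactors = FALSE)
}

# Chronic stream: 5 monthly packs starting ~180 days before index, covering
# 150 days of daily dose (>= 90-day threshold). adherence_noise drops packs.
.disp_chronic <- function(ids, idx, atc, cfg) {
  n <- length(ids)
  if (n == 0) return(.empty_dispensings())
  d <- cfg$dispensing
  npack <- 5L
  start <- sample(0:2, n, replace = TRUE)
  pid <- rep(ids, each = npack)
  dt <- rep(idx, each = npack) - 180 + rep(start, each = npack) +
    rep(0:(npack - 1), times = n) * d$gap_days +
    sample(-2:2, n * npack, replace = TRUE)
  keep <- stats::runif(n * npack) >= d$adherence_noise
  data.frame(patient_id = pid[keep], date = dt[keep], atc_code = atc,
             packs = 1, units_per_pack = d$pack_size, daily_dose = 1,
             stringsAsFactors = FALSE)
}

# Short non-chronic stream (1-2 packs, < 90 covered days).
.disp_nonchronic <- function(ids, idx, atc, cfg) {
  n <- length(ids)
  if (n == 0) return(.empty_dispensings())
  k <- sample(1:2, n, replace = TRUE)
  pid <- rep(ids, k)
  dt <- rep(idx, k) - sample.int(183, sum(k), replace = TRUE)
  data.frame(patient_id = pid, date = dt, atc_code = atc, packs = 1,
             units_per_pack = cfg$dispensing$pack_size, daily_dose = 1,
             stringsAsFactors = FALSE)
}

.drug_dispensings <- function(ids, idx, atc, chronic, cfg) {
  non <- !chronic & stats::runif(length(ids)) < cfg$dispensing$nonchronic_frac
  rbind(.disp_chronic(ids[chronic], idx[chronic], atc, cfg),
        .disp_nonchronic(ids[non], idx[non], atc, cfg))
}

# --- main generator --------------------------------------------------------

#' Generate a synthetic claims cohort with known causal ground truth
#'
#' Simulates patients from the structural model described in
#' [cohort_config()] and lays the result out as claims-style tables:
#' `patients` (demographics, index/death dates), `dispensings` (drug delivery
#' events for the index drug, background drugs and any screen drugs),
#' `code_events` (diagnosis codes for the comorbid conditions plus unmapped
#' noise codes), `care_events` (initial treatments and recurrence proxies),
#' `tumors` (subtype, nodal status, treatment flags) and `truth`
#' (per-patient true exposure, latent event time and censoring time, plus the
#' true comorbidity indicators).
#'
#' Calendar layout: each patient's administrative follow-up (uniform on
#' `admin_months`) is converted to an index date counted back from
#' `cutoff_os`, which reproduces staggered-entry censoring without calendar
#' bookkeeping. `detail = "cohort"` skips the claims-detail tables
#' (dispensings, code and care events) for fast simulation studies; the
#' patient-level draws are identical in both modes.
#'
#' @param config a [cohort_config()].
#' @param detail `"full"` for all claims tables, `"cohort"` for the fast
#'   patient-level tables only.
#' @return an object of class `claims_dataset`: a list of the six tables plus
#'   the generating config.
#' @export
generate_cohort <- function(config, detail = c("full", "cohort")) {
  detail <- match.arg(detail)
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_patients
  with_seed(cfg$seed, {
    cov <- .sim_covariates(n, cfg)
    X <- cov$X
    ids <- sprintf("P%07d", seq_len(n))

    lp_a <- .check_lp(cfg$alpha[1] + drop(X %*% cfg$alpha[-1]),
                      "exposure model")
    A <- stats::rbinom(n, 1, expit(lp_a))

    # screen drugs: independent confounded exposures sharing alpha
    sdg <- cfg$screen_drugs
    extra_eta <- 0
    A_screen <- NULL
    if (!is.null(sdg) && nrow(sdg) > 0) {
      shift <- if ("alpha_shift" %in% names(sdg)) sdg$alpha_shift else 0
      A_screen <- vapply(seq_len(nrow(sdg)), function(j) {
        stats::rbinom(n, 1, expit(lp_a + rep(shift, length.out = nrow(sdg))[j]))
      }, integer(n))
      if (n == 0) A_screen <- matrix(integer(0), 0, nrow(sdg))
      colnames(A_screen) <- sdg$atc
      extra_eta <- drop(A_screen %*% sdg$beta)
    }

    m1 <- .sim_subtype(A, X, cfg)
    m2 <- .sim_node(A, X, m1, cfg)
    eta <- .hazard_lp(A, X, m1, m2, cfg, extra = extra_eta)
    t_event <- .sim_event_time(eta, cfg)
    admin <- stats::runif(n, cfg$admin_months[1], cfg$admin_months[2])
    dropout <- if (cfg$dropout_rate > 0) stats::rexp(n, cfg$dropout_rate)
               else rep(Inf, n)
    t_censor <- pmin(admin, dropout)

    index_date <- cfg$cutoff_os - round(admin * DAYS_PER_MONTH) -
      cfg$surgery_gap_days
    surgery_date <- index_date + cfg$surgery_gap_days
    # deaths after dropout are unrecorded; the extract ends at the cutoff
    death_date <- as.Date(rep(NA, n))
    death_observable <- t_event <= dropout
    death_date[death_observable] <-
      surgery_date[death_observable] +
      round(t_event[death_observable] * DAYS_PER_MONTH)
    death_date[!is.na(death_date) & death_date > cfg$cutoff_os] <- NA

    patients <- data.frame(
      patient_id = ids, index_date = index_date, age = cov$age,
      deprivation = cov$deprivation, gp_visits = cov$gp_visits,
      gyn_visits = cov$gyn_visits, screening = cov$screening,
      death_date = death_date, stringsAsFactors = FALSE)

    subtype <- factor(SUBTYPE_LEVELS[m1], levels = SUBTYPE_LEVELS)
    chemo <- stats::rbinom(n, 1, expit(-0.6 + 1.5 * (m1 == 2) +
                                         1.0 * (m1 == 3) + 0.8 * m2)) == 1
    endocrine <- stats::rbinom(n, 1, ifelse(m1 %in% c(1L, 4L), 0.85, 0.1)) == 1
    tumors <- data.frame(patient_id = ids, subtype = subtype,
                         node_positive = m2 == 1L, chemo = chemo,
                         endocrine = endocrine, stringsAsFactors = FALSE)

    truth <- data.frame(
      patient_id = ids, true_exposure = A == 1L,
      true_event_time = t_event, true_censor_time = t_censor,
      comorb_cardiovascular = cov$comorbs$cardiovascular,
      comorb_metabolic = cov$comorbs$metabolic,
      comorb_psychiatric = cov$comorbs$psychiatric,
      stringsAsFactors = FALSE)

    if (detail == "full") {
      disp <- list(.drug_dispensings(ids, index_date, cfg$index_atc,
                                     A == 1L, cfg))
      if (cfg$n_background_drugs > 0) {
        ncom <- cov$comorbs$cardiovascular + cov$comorbs$metabolic +
          cov$comorbs$psychiatric
        z_age <- X[, "age_z"]
        for (j in seq_len(cfg$n_background_drugs)) {
          atc <- sprintf("Z%02dAA%02d", j %% 100, j %% 100)
          chron <- stats::rbinom(n, 1, expit(-2 + 0.6 * ncom + 0.3 * z_age)) == 1
          disp[[length(disp) + 1]] <-
            .drug_dispensings(ids, index_date, atc, chron, cfg)
        }
      }
      if (!is.null(A_screen)) {
        for (j in seq_len(ncol(A_screen))) {
          disp[[length(disp) + 1]] <-
            .drug_dispensings(ids, index_date, colnames(A_screen)[j],
                              A_screen[, j] == 1L, cfg)
        }
      }
      dispensings <- do.call(rbind, disp)
      rownames(dispensings) <- NULL

      # diagnosis codes for true comorbid conditions, within every timeframe
      ce <- list()
      code_for <- c(cardiovascular = "DX_CARDIO", metabolic = "DX_METAB",
                    psychiatric = "DX_PSY")
      for (cond in names(code_for)) {
        has <- which(cov$comorbs[[cond]])
        if (length(has))
          ce[[cond]] <- data.frame(
            patient_id = ids[has],
            date = index_date[has] - sample(0:330, length(has), replace = TRUE),
            code = code_for[[cond]], source = "diagnosis",
            stringsAsFactors = FALSE)
      }
      noisy <- which(stats::runif(n) < 0.05)
      if (length(noisy))
        ce$noise <- data.frame(
          patient_id = ids[noisy],
          date = index_date[noisy] - sample(0:330, length(noisy), replace = TRUE),
          code = "DX_UNMAPPED", source = "diagnosis", stringsAsFactors = FALSE)
      code_events <- if (length(ce)) do.call(rbind, ce) else
        data.frame(patient_id = character(0), date = as.Date(character(0)),
                   code = character(0), source = character(0),
                   stringsAsFactors = FALSE)
      rownames(code_events) <- NULL

      care_events <- .sim_care_events(ids, surgery_date, chemo, t_event,
                                      t_censor, cfg)
    } else {
      dispensings <- .empty_dispensings()
      code_events <- data.frame(patient_id = character(0),
                                date = as.Date(character(0)),
                                code = character(0), source = character(0),
                                stringsAsFactors = FALSE)
      care_events <- .empty_care_events()
    }

    structure(list(patients = patients, dispensings = dispensings,
                   code_events = code_events, care_events = care_events,
                   tumors = tumors, truth = truth, config = cfg),
              class = "claims_dataset")
  })
}

.empty_care_events <- function() {
  data.frame(patient_id = character(0), date = as.Date(character(0)),
             kind = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

# Initial treatments (surgery, chemotherapy, radiotherapy around surgery) and
# recurrence proxies for a fraction of observed deaths.
.sim_care_events <- function(ids, surgery_date, chemo, t_event, t_censor, cfg) {
  n <- length(ids)
  if (n == 0) return(.empty_care_events())
  ev <- list(data.frame(patient_id = ids, date = surgery_date,
                        kind = "breast_surgery", detail = "initial",
                        stringsAsFactors = FALSE))
  ch <- which(chemo)
  if (length(ch)) {
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = rep(ids[ch], 2),
      date = c(surgery_date[ch] + 30, surgery_date[ch] + 150),
      kind = rep(c("chemo_start", "chemo_end"), each = length(ch)),
      detail = "initial", stringsAsFactors = FALSE)
  }
  rt <- which(stats::runif(n) < 0.85)
  if (length(rt)) {
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = rep(ids[rt], 2),
      date = c(surgery_date[rt] + 60, surgery_date[rt] + 152),
      kind = rep(c("radiotherapy_start", "radiotherapy_end"),
                 each = length(rt)),
      detail = "initial", stringsAsFactors = FALSE)
  }
  died <- t_event <= t_censor
  rec <- which(died & stats::runif(n) < cfg$recurrence_frac)
  if (length(rec)) {
    r_months <- t_event[rec] * stats::runif(length(rec), 0.5, 0.9)
    kinds <- sample(c("chemo_start", "metastatic_drug", "metastasis_code"),
                    length(rec), replace = TRUE)
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = ids[rec],
      date = surgery_date[rec] + round(r_months * DAYS_PER_MONTH),
      kind = kinds, detail = "recurrence", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>", nrow(x$patients), "patients,",
      nrow(x$dispensings), "dispensings,", nrow(x$code_events),
      "code events,", nrow(x$care_events), "care events\n")
  invisible(x)
}

#' Analysis table straight from the generator's ground truth
#'
#' Bypasses the claims-coding layer: exposure, comorbidity indicators,
#' covariates, mediators and overall-survival outcomes are taken from the
#' `truth`, `patients` and `tumors` tables. This is the fast path for
#' simulation studies of the causal engine, where the exposure-coding layer
#' itself is not under study.
#'
#' @param dataset a `claims_dataset`.
#' @return data.frame with columns `patient_id`, `exposure`, the standardized
#'   covariates of [cohort_config()], `subtype`, `node`, `os_time`,
#'   `os_event`; covariate column names in attribute `"covariates"`.
#' @export
analysis_cohort_from_truth <- function(dataset) {
  stopifnot(inherits(dataset, "claims_dataset"))
  p <- dataset$patients; tr <- dataset$truth; tu <- dataset$tumors
  cfg <- dataset$config
  X <- .design_matrix(p$age, p$deprivation, p$gp_visits, p$gyn_visits,
                      p$screening,
                      list(cardiovascular = tr$comorb_cardiovascular,
                           metabolic = tr$comorb_metabolic,
                           psychiatric = tr$comorb_psychiatric), cfg)
  out <- data.frame(patient_id = p$patient_id,
                    exposure = as.integer(tr$true_exposure),
                    X,
                    subtype = tu$subtype,
                    node = as.integer(tu$node_positive),
                    os_time = pmin(tr$true_event_time, tr$true_censor_time),
                    os_event = as.integer(tr$true_event_time <=
                                            tr$true_censor_time),
                    stringsAsFactors = FALSE)
  attr(out, "covariates") <- COVARIATE_NAMES
  out
}
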