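# Configuration objects: the structural-causal-model cohort configuration and
# the chronic-exposure coding rules.

# Names of the standardized pre-exposure covariates entering every linear
# predictor of the structural model, in fixed order.
COVARIATE_NAMES <- c("age_z", "deprivation_c", "gp_visits_c", "gyn_visits_c",
                     "screening", "comorb_cardiovascular", "comorb_metabolic",
                     "comorb_psychiatric")

SUBTYPE_LEVELS <- c("luminal", "tnbc", "her2", "undefined")

#' Configuration of the synthetic claims cohort generator
#'
#' Defines a structural causal model over pre-exposure covariates C, a binary
#' chronic drug exposure A, two causally ordered mediators (tumor subtype M1,
#' nodal status M2), and a Weibull proportional-hazards event time T, with the
#' ordering C -> A -> M1 -> M2 -> T and C entering every downstream equation.
#' The generator emits claims-style tables (patients, dispensings, diagnosis
#' code events, care events, tumors) plus a ground-truth table, so every
#' estimator in the package can be checked against a known estimand.
#'
#' Covariates are standardized before entering linear predictors: age as
#' (age - age_mean)/age_sd, deprivation quintile as (q - 3)/2, GP visits as
#' (visits - 5)/5, gynecologist visits as visits - 0.7; the screening flag and
#' comorbidity indicators enter as 0/1. Coefficient vectors are indexed by
#' these standardized names.
#'
#' Defaults describe a confounded observational cohort: age, care utilization
#' and comorbidity drive both exposure (through `alpha`) and the hazard
#' (through `beta$covariates`), while the exposure -> mediator couplings are
#' zero so that the configured subtype and nodal baselines are exactly the
#' marginal frequencies. Mediation scenarios switch those couplings on; see
#' [scenario_config()].
#'
#' @param n_patients number of patients to simulate (0 gives empty tables).
#' @param seed integer seed; identical config + seed reproduces every table
#'   bit-identically.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age distribution
#'   (years).
#' @param gamma named list of comorbidity prevalence coefficients, one
#'   `c(intercept, age_z slope)` pair per condition (log-odds scale).
#' @param alpha exposure-model coefficients: named vector
#'   `c(intercept, <covariates>)` on the log-odds scale.
#' @param subtype_baseline baseline subtype probabilities for
#'   luminal/TNBC/HER2+/undefined; must sum to 1.
#' @param kappa_m1 3 x (2 + 8) matrix of multinomial-logit coefficients for
#'   the non-reference subtype levels (rows tnbc/her2/undefined; columns
#'   intercept, exposure, covariates). Default: intercepts matching
#'   `subtype_baseline`, zero exposure and covariate effects.
#' @param node_baseline baseline probability of node-positive disease.
#' @param kappa_m2 named vector of nodal-status logit coefficients
#'   (intercept, exposure, tnbc, her2, undefined, covariates). Default:
#'   intercept `qlogis(node_baseline)`, all else zero.
#' @param beta hazard log-effects: list with `exposure` (scalar), `subtype`
#'   (named vector tnbc/her2/undefined; luminal is reference), `node`
#'   (scalar), `covariates` (named vector).
#' @param weibull_shape,weibull_rate Weibull baseline hazard
#'   `h0(t) = rate * shape * t^(shape-1)`, time in months; both must be > 0.
#' @param admin_months administrative censoring window `c(min, max)` in
#'   months; each patient's cutoff is uniform on it (staggered accrual).
#' @param dropout_rate exponential loss-to-follow-up rate per month (0 for
#'   none).
#' @param dispensing list: `gap_days` between dispensings, `pack_size` units
#'   per pack, `adherence_noise` probability that a scheduled pack is skipped,
#'   `nonchronic_frac` fraction of unexposed patients with a short
#'   (sub-threshold) dispensing stream.
#' @param n_background_drugs number of additional drugs, with
#'   comorbidity-linked prevalence and no hazard effect, feeding the
#'   medication-count covariate.
#' @param screen_drugs optional data.frame(`atc`, `beta`, `alpha_shift`) of
#'   extra screened drugs: each gets an independent confounded exposure
#'   (`alpha` shifted by `alpha_shift` on the intercept) and contributes
#'   `beta` * exposure to the log-hazard.
#' @param index_atc ATC code (symbolic) of the index drug carrying exposure A.
#' @param recurrence_frac fraction of observed deaths preceded by an emitted
#'   recurrence-proxy care event.
#' @param surgery_gap_days days from diagnosis (index) date to first breast
#'   surgery.
#' @param cutoff_os,cutoff_dfs administrative calendar cutoffs used when
#'   laying out calendar dates.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [scenario_config()], [true_marginal_hr()]
#' @export
cohort_config <- function(n_patients = 10000,
                          seed = 1L,
                          age_mean = 60, age_sd = 12, age_min = 18, age_max = 95,
                          gamma = list(cardiovascular = c(-1.1, 0.9),
                                       metabolic = c(-1.3, 0.7),
                                       psychiatric = c(-1.9, 0.15)),
                          alpha = c(intercept = -1.3, age_z = 0.55,
                                    deprivation_c = 0.10, gp_visits_c = 0.35,
                                    gyn_visits_c = 0.00, screening = 0.10,
                                    comorb_cardiovascular = 0.50,
                                    comorb_metabolic = 0.40,
                                    comorb_psychiatric = 0.30),
                          subtype_baseline = c(luminal = 0.65, tnbc = 0.08,
                                               her2 = 0.08, undefined = 0.19),
                          kappa_m1 = NULL,
                          node_baseline = 0.19,
                          kappa_m2 = NULL,
                          beta = list(exposure = log(0.8),
                                      subtype = c(tnbc = 0.80, her2 = 0.25,
                                                  undefined = 0.10),
                                      node = 0.60,
                                      covariates = c(age_z = 0.70,
                                                     deprivation_c = 0.05,
                                                     gp_visits_c = 0.10,
                                                     gyn_visits_c = 0.00,
                                                     screening = -0.05,
                                                     comorb_cardiovascular = 0.30,
                                                     comorb_metabolic = 0.20,
                                                     comorb_psychiatric = 0.10)),
                          weibull_shape = 1.1,
                          weibull_rate = 0.002,
                          admin_months = c(36, 98),
                          dropout_rate = 0.001,
                          dispensing = list(gap_days = 30, pack_size = 30,
                                            adherence_noise = 0,
                                            nonchronic_frac = 0.4),
                          n_background_drugs = 5L,
                          screen_drugs = NULL,
                          index_atc = "C00AA01",
                          recurrence_frac = 0.5,
                          surgery_gap_days = 30,
                          cutoff_os = as.Date("2019-03-01"),
                          cutoff_dfs = as.Date("2018-12-30")) {
  if (node_baseline <= 0 || node_baseline >= 1)
    stop_pharmscreen("node_baseline must be in (0,1)")
  if (any(subtype_baseline <= 0) || abs(sum(subtype_baseline) - 1) > 1e-8)
    stop_pharmscreen("subtype baseline probabilities must be in (0,1) and sum to 1")
  if (is.null(kappa_m1)) {
    kappa_m1 <- matrix(0, nrow = 3, ncol = 2 + length(COVARIATE_NAMES),
                       dimnames = list(SUBTYPE_LEVELS[-1],
                                       c("intercept", "exposure", COVARIATE_NAMES)))
    kappa_m1[, "intercept"] <- log(subtype_baseline[SUBTYPE_LEVELS[-1]] /
                                     subtype_baseline["luminal"])
  }
  if (is.null(kappa_m2)) {
    kappa_m2 <- stats::setNames(
      numeric(5 + length(COVARIATE_NAMES)),
      c("intercept", "exposure", SUBTYPE_LEVELS[-1], COVARIATE_NAMES))
    kappa_m2["intercept"] <- stats::qlogis(node_baseline)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min, age_max = age_max,
    gamma = gamma, alpha = alpha,
    subtype_baseline = subtype_baseline, kappa_m1 = kappa_m1,
    node_baseline = node_baseline, kappa_m2 = kappa_m2,
    beta = beta,
    weibull_shape = weibull_shape, weibull_rate = weibull_rate,
    admin_months = admin_months, dropout_rate = dropout_rate,
    dispensing = dispensing,
    n_background_drugs = as.integer(n_background_drugs),
    screen_drugs = screen_drugs,
    index_atc = index_atc, recurrence_frac = recurrence_frac,
    surgery_gap_days = surgery_gap_days,
    cutoff_os = as.Date(cutoff_os), cutoff_dfs = as.Date(cutoff_dfs)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 0)
    stop_pharmscreen("n_patients must be a non-negative count")
  if (cfg$weibull_shape <= 0 || cfg$weibull_rate <= 0)
    stop_pharmscreen("Weibull shape and rate must be strictly positive")
  if (abs(sum(cfg$subtype_baseline) - 1) > 1e-8)
    stop_pharmscreen("subtype baseline probabilities must sum to 1")
  if (any(cfg$subtype_baseline <= 0))
    stop_pharmscreen("subtype baseline probabilities must be in (0,1)")
  if (cfg$node_baseline <= 0 || cfg$node_baseline >= 1)
    stop_pharmscreen("node_baseline must be in (0,1)")
  if (length(cfg$admin_months) != 2 || any(cfg$admin_months <= 0) ||
      cfg$admin_months[1] > cfg$admin_months[2])
    stop_pharmscreen("admin_months must be a positive c(min, max) window")
  if (cfg$dropout_rate < 0)
    stop_pharmscreen("dropout_rate must be non-negative")
  if (cfg$dispensing$adherence_noise < 0 || cfg$dispensing$adherence_noise >= 1)
    stop_pharmscreen("adherence_noise must be in [0,1)")
  if (length(cfg$alpha) != 1 + length(COVARIATE_NAMES))
    stop_pharmscreen("alpha must have an intercept plus one term per covariate")
  if (!is.null(cfg$screen_drugs)) {
    sd <- cfg$screen_drugs
    if (!all(c("atc", "beta") %in% names(sd)))
      stop_pharmscreen("screen_drugs needs columns atc and beta")
    if (anyDuplicated(sd$atc)) stop_pharmscreen("screen_drugs atc codes must be unique")
  }
  invisible(cfg)
}

#' Preset generator configurations for mediation scenarios
#'
#' Returns a [cohort_config()] in which the exposure acts through a single
#' named channel, for use as ground truth in estimator-recovery studies:
#' \describe{
#'   \item{direct}{exposure affects the hazard only (no mediator coupling).}
#'   \item{node}{exposure shifts nodal status only (`beta$exposure = 0`).}
#'   \item{subtype}{exposure shifts the subtype distribution only.}
#'   \item{null}{exposure has no causal channel at all; assignment is still
#'     confounded, so crude contrasts remain biased.}
#' }
#'
#' @param scenario one of "direct", "node", "subtype", "null".
#' @param n_patients,seed passed to [cohort_config()].
#' @param ... further overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
scenario_config <- function(scenario = c("direct", "node", "subtype", "null"),
                            n_patients = 10000, seed = 1L, ...) {
  scenario <- match.arg(scenario)
  cfg <- cohort_config(n_patients = n_patients, seed = seed, ...)
  cfg$beta$exposure <- 0
  switch(scenario,
    direct = { cfg$beta$exposure <- log(0.7) },
    node = { cfg$kappa_m2["exposure"] <- log(3) },
    subtype = {
      cfg$kappa_m1["tnbc", "exposure"] <- 0.9
      cfg$kappa_m1["undefined", "exposure"] <- 0.3
    },
    null = { }
  )
  validate_cohort_config(cfg)
  cfg
}

#' Chronic-exposure coding rules
#'
#' Encodes the exposure phenotype: a patient is chronically exposed to a drug
#' when the dispensings in the lookback window before diagnosis cover at least
#' `min_covered_days` days of full dose. The window is
#' `[index - window_days, index - 1]`; the index date itself is excluded.
#' Covered days from overlapping dispensings accumulate (stockpiling) but are
#' capped at the window length.
#'
#' @param window_days lookback length in days (default 183, i.e. six months).
#' @param min_covered_days full-dose coverage threshold (default 90, i.e.
#'   three months).
#' @param dose_rules named list mapping ATC code to units per day (drugs
#'   absent from the list default to 1 unit/day).
#' @param exclusions character vector of ATC prefixes excluded from screening
#'   (diagnostic agents, antineoplastics, non-systemic preparations).
#' @param combination_map named list mapping a combination-product ATC code to
#'   the character vector of its component codes; combination dispensings are
#'   split into one dispensing per component.
#' @return an object of class `exposure_rules`.
#' @export
exposure_rules <- function(window_days = 183L,
                           min_covered_days = 90L,
                           dose_rules = list(),
                           exclusions = c("V04", "V08", "L01"),
                           combination_map = list()) {
  if (!(window_days >= min_covered_days && min_covered_days > 0))
    stop_pharmscreen("need window_days >= min_covered_days > 0")
  keys <- c(exclusions, names(combination_map))
  if (length(keys) && !all(is_valid_atc(keys)))
    stop_pharmscreen("exclusions and combination_map keys must be valid ATC codes")
  if (length(combination_map) && any(lengths(combination_map) == 0))
    stop_pharmscreen("combination_map components must be non-empty")
  structure(list(window_days = as.integer(window_days),
                 min_covered_days = as.integer(min_covered_days),
                 dose_rules = dose_rules,
                 exclusions = exclusions,
                 combination_map = combination_map),
            class = "exposure_rules")
}

#' Default diagnosis-code map for the synthetic cohorts
#'
#' Maps the symbolic diagnosis tokens emitted by [generate_cohort()] to
#' comorbid-condition labels. Real deployments supply their own map from
#' ICD-10/procedure codes to conditions.
#'
#' @return named character vector, code -> condition.
#' @export
default_code_map <- function() {
  c(DX_CARDIO = "cardiovascular",
    DX_METAB = "metabolic",
    DX_PSY = "psychiatric")
}
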