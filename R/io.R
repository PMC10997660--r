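# Reading and writing the claims tables and the generator configuration.

CLAIMS_TABLES <- c("patients", "dispensings", "code_events", "care_events",
                   "tumors", "truth")

.date_cols <- list(patients = c("index_date", "death_date"),
                   dispensings = "date", code_events = "date",
                   care_events = "date")

#' Write a claims dataset to disk
#'
#' One file per table, as RFC-4180 CSV with ISO-8601 dates (`format =
#' "csv"`) or as Parquet columnar files (`format = "parquet"`, requires the
#' arrow package).
#'
#' @param dataset a `claims_dataset`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return invisibly, the files written.
#' @export
write_claims <- function(dataset, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(CLAIMS_TABLES, function(nm) {
    p <- file.path(dir, paste0(nm, ".", format))
    if (format == "csv") {
      utils::write.csv(dataset[[nm]], p, row.names = FALSE, na = "")
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop_pharmscreen("parquet output requires the arrow package")
      arrow::write_parquet(dataset[[nm]], p)
    }
    p
  }, character(1))
  invisible(paths)
}

#' Read a claims dataset from disk
#'
#' Counterpart of [write_claims()]; restores column classes (dates, logical
#' flags, subtype factor levels).
#'
#' @param dir directory containing the table files.
#' @param format `"csv"` or `"parquet"`.
#' @return a `claims_dataset` (without the generating config).
#' @export
read_claims <- function(dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  tabs <- lapply(CLAIMS_TABLES, function(nm) {
    p <- file.path(dir, paste0(nm, ".", format))
    if (!file.exists(p)) stop_pharmscreen("missing table file: ", p)
    d <- if (format == "csv") {
      utils::read.csv(p, stringsAsFactors = FALSE)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stop_pharmscreen("parquet input requires the arrow package")
      as.data.frame(arrow::read_parquet(p))
    }
    for (dc in .date_cols[[nm]] %||% character(0))
      if (dc %in% names(d)) d[[dc]] <- as.Date(d[[dc]])
    d
  })
  names(tabs) <- CLAIMS_TABLES
  for (lc in c("screening")) {
    if (lc %in% names(tabs$patients))
      tabs$patients[[lc]] <- as.logical(tabs$patients[[lc]])
  }
  for (lc in c("node_positive", "chemo", "endocrine"))
    tabs$tumors[[lc]] <- as.logical(tabs$tumors[[lc]])
  tabs$tumors$subtype <- factor(tabs$tumors$subtype, levels = SUBTYPE_LEVELS)
  for (lc in grep("^true_exposure$|^comorb_", names(tabs$truth), value = TRUE))
    tabs$truth[[lc]] <- as.logical(tabs$truth[[lc]])
  structure(c(tabs, list(config = NULL)), class = "claims_dataset")
}

#' Write a cohort configuration as YAML
#'
#' @param config a [cohort_config()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  # yaml drops names on atomic vectors; store named vectors as maps
  x$alpha <- as.list(x$alpha)
  x$subtype_baseline <- as.list(x$subtype_baseline)
  x$kappa_m2 <- as.list(x$kappa_m2)
  x$beta <- list(exposure = x$beta$exposure,
                 subtype = as.list(x$beta$subtype),
                 node = x$beta$node,
                 covariates = as.list(x$beta$covariates))
  x$kappa_m1 <- list(rows = rownames(x$kappa_m1),
                     cols = colnames(x$kappa_m1),
                     values = as.vector(x$kappa_m1))
  x$cutoff_os <- format(x$cutoff_os)
  x$cutoff_dfs <- format(x$cutoff_dfs)
  if (!is.null(x$screen_drugs)) x$screen_drugs <- as.list(x$screen_drugs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' @param path file written by [write_cohort_config()].
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  km1 <- matrix(x$kappa_m1$values, nrow = length(x$kappa_m1$rows),
                dimnames = list(x$kappa_m1$rows, x$kappa_m1$cols))
  args <- list(
    n_patients = x$n_patients, seed = x$seed,
    age_mean = x$age_mean, age_sd = x$age_sd,
    age_min = x$age_min, age_max = x$age_max,
    gamma = lapply(x$gamma, unlist),
    alpha = unlist(x$alpha),
    subtype_baseline = unlist(x$subtype_baseline),
    kappa_m1 = km1,
    node_baseline = x$node_baseline,
    kappa_m2 = unlist(x$kappa_m2),
    beta = list(exposure = x$beta$exposure,
                subtype = unlist(x$beta$subtype),
                node = x$beta$node,
                covariates = unlist(x$beta$covariates)),
    weibull_shape = x$weibull_shape, weibull_rate = x$weibull_rate,
    admin_months = unlist(x$admin_months), dropout_rate = x$dropout_rate,
    dispensing = x$dispensing,
    n_background_drugs = x$n_background_drugs,
    screen_drugs = if (!is.null(x$screen_drugs))
      as.data.frame(x$screen_drugs, stringsAsFactors = FALSE),
    index_atc = x$index_atc, recurrence_frac = x$recurrence_frac,
    surgery_gap_days = x$surgery_gap_days,
    cutoff_os = as.Date(x$cutoff_os), cutoff_dfs = as.Date(x$cutoff_dfs))
  do.call(cohort_config, args)
}
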