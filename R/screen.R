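# End-to-end drug-wide screen: per drug PS -> weights -> balance gate ->
# weighted Cox ATE; across drugs BH; mediation for raw-significant drugs;
# weighted KM + adjusted log-rank for BH-significant drugs.

#' Screen configuration
#'
#' Collects the thresholds and knobs of the drug-wide screen. Defaults are
#' the pipeline's printed constants: SMD gate 0.1, Wald significance 0.05,
#' BH level 0.05 per endpoint, adjusted log-rank threshold 0.1, minimum 300
#' exposed patients.
#'
#' @param endpoints endpoints to run ("os", "dfs" or both).
#' @param rules an [exposure_rules()].
#' @param code_map comorbidity code map.
#' @param timeframe comorbidity timeframe.
#' @param smd_threshold balance-gate threshold on |SMD|.
#' @param alpha raw Wald significance level (selects drugs for mediation).
#' @param bh_q Benjamini-Hochberg level per endpoint.
#' @param logrank_alpha adjusted log-rank threshold.
#' @param min_exposed minimum exposed count per screened drug.
#' @param top_k_coexposure co-exposure indicators entering the PS model.
#' @param run_pse,run_km switch the mediation / survival-curve stages.
#' @param pse_cap cap quantile for mediator-ratio weights.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(endpoints = c("os", "dfs"),
                          rules = exposure_rules(),
                          code_map = default_code_map(),
                          timeframe = "primary",
                          smd_threshold = 0.1,
                          alpha = 0.05,
                          bh_q = 0.05,
                          logrank_alpha = 0.1,
                          min_exposed = 300,
                          top_k_coexposure = 20,
                          run_pse = TRUE,
                          run_km = TRUE,
                          pse_cap = 0.99) {
  endpoints <- match.arg(endpoints, c("os", "dfs"), several.ok = TRUE)
  for (x in c(smd_threshold, alpha, bh_q, logrank_alpha))
    if (x <= 0 || x >= 1) stop_pharmscreen("thresholds must be in (0,1)")
  structure(list(endpoints = endpoints, rules = rules, code_map = code_map,
                 timeframe = timeframe, smd_threshold = smd_threshold,
                 alpha = alpha, bh_q = bh_q, logrank_alpha = logrank_alpha,
                 min_exposed = min_exposed,
                 top_k_coexposure = top_k_coexposure,
                 run_pse = run_pse, run_km = run_km, pse_cap = pse_cap),
            class = "screen_config")
}

.endpoint_cols <- function(ep) {
  if (ep == "os") c("os_time", "os_event") else c("dfs_time", "dfs_event")
}

#' Run the drug-wide survival screen
#'
#' Executes the full pipeline on a claims dataset (or a pre-built
#' [build_cohort_frame()]): for every eligible drug and endpoint, a
#' propensity model on the pre-exposure adjustment set, stabilized IPT
#' weights, the SMD balance gate (failing drugs are retained in the output
#' with their gate status but excluded downstream), and the weighted Cox
#' ATE; Benjamini-Hochberg correction per endpoint across gate-passing
#' drugs; path-specific effect decomposition for drugs with a raw-significant
#' ATE; weighted Kaplan-Meier curves and the adjusted log-rank test for
#' BH-significant drugs. Per-drug model failures are recorded in the results
#' table and never abort the screen. Output is deterministic given the input
#' data (drugs processed in sorted ATC order).
#'
#' @param dataset a `claims_dataset` or `cohort_frame`.
#' @param config a [screen_config()].
#' @param out_dir optional directory; when given, the results, balance
#'   reports and a run manifest are written there (see
#'   [write_screen_report()]).
#' @return object of class `screen_result`: `results` (one row per drug x
#'   endpoint), `balance` (named list of balance reports), `pse` (named list
#'   of decompositions), `km` (named list of curve tables), `logrank`
#'   (named list), `eligible`, `config`.
#' @export
run_screen <- function(dataset, config = screen_config(), out_dir = NULL) {
  frame <- if (inherits(dataset, "cohort_frame")) dataset else
    build_cohort_frame(dataset, rules = config$rules,
                       code_map = config$code_map,
                       timeframe = config$timeframe,
                       min_exposed = config$min_exposed)
  drugs <- frame$eligible
  balance <- list(); rows <- list()
  weights_store <- list(); tables_store <- list()

  for (drug in drugs) {
    tab <- analysis_table_for_drug(frame, drug, config$top_k_coexposure)
    covs <- attr(tab, "covariates")
    res_base <- data.frame(drug = drug, gate = NA, max_abs_smd = NA_real_,
                           failure = NA_character_, stringsAsFactors = FALSE)
    step <- tryCatch({
      ps <- estimate_propensity(tab[covs], tab$exposure)
      sw <- stabilized_weights(ps, tab$exposure)
      bal <- balance_report(tab[covs], tab$exposure, sw,
                            threshold = config$smd_threshold)
      list(ps = ps, sw = sw, bal = bal)
    }, error = function(e) e)
    if (inherits(step, "error")) {
      res_base$failure <- conditionMessage(step)
      for (ep in config$endpoints)
        rows[[paste(drug, ep)]] <- cbind(res_base, endpoint = toupper(ep))
      next
    }
    balance[[drug]] <- step$bal
    gate <- attr(step$bal, "pass")
    res_base$gate <- gate
    res_base$max_abs_smd <- attr(step$bal, "max_abs_smd")
    weights_store[[drug]] <- step$sw
    tables_store[[drug]] <- tab
    for (ep in config$endpoints) {
      cols <- .endpoint_cols(ep)
      row <- res_base
      row$endpoint <- toupper(ep)
      if (gate) {
        ate <- tryCatch(
          weighted_cox_ate(tab[[cols[1]]], tab[[cols[2]]], tab$exposure,
                           step$sw, endpoint = toupper(ep), drug = drug),
          error = function(e) e)
        if (inherits(ate, "error")) {
          row$failure <- conditionMessage(ate)
        } else if (!ate$converged) {
          row$failure <- "non-convergence"
        } else {
          row <- cbind(row,
                       ate[c("hr", "log_hr", "robust_se", "ci_lower",
                             "ci_upper", "p_value", "n_exposed",
                             "n_unexposed", "n_events")])
        }
      }
      rows[[paste(drug, ep)]] <- row
    }
  }

  results <- if (length(rows)) .rbind_fill(rows) else
    data.frame(drug = character(0), endpoint = character(0),
               gate = logical(0))

  # BH per endpoint across gate-passing, converged drugs
  results$p_adjusted <- rep(NA_real_, nrow(results))
  results$bh_reject <- rep(NA, nrow(results))
  if (nrow(results) && "p_value" %in% names(results)) {
    for (ep in toupper(config$endpoints)) {
      sel <- which(results$endpoint == ep & !is.na(results$p_value) &
                     results$gate %in% TRUE)
      if (length(sel)) {
        bh <- benjamini_hochberg(results$p_value[sel], config$bh_q)
        results$p_adjusted[sel] <- bh$adjusted
        results$bh_reject[sel] <- bh$reject
      }
    }
    results$raw_significant <- !is.na(results$p_value) &
      results$p_value < config$alpha
  }

  pse <- list(); km <- list(); logrank <- list()
  if (nrow(results) && "p_value" %in% names(results)) {
    for (i in seq_len(nrow(results))) {
      drug <- results$drug[i]; ep <- results$endpoint[i]
      cols <- .endpoint_cols(tolower(ep))
      tab <- tables_store[[drug]]
      if (is.null(tab)) next
      key <- paste(drug, ep, sep = ".")
      if (config$run_pse && isTRUE(results$raw_significant[i])) {
        dec <- tryCatch({
          models <- fit_mediator_models(tab, attr(tab, "covariates"))
          path_specific_effects(tab, models, weights_store[[drug]],
                                time = cols[1], event = cols[2],
                                cap = config$pse_cap, drug = drug,
                                endpoint = ep)
        }, error = function(e) NULL)
        if (!is.null(dec) && dec$converged) pse[[key]] <- dec
      }
      if (config$run_km && isTRUE(results$bh_reject[i])) {
        grp <- ifelse(tab$exposure == 1, "exposed", "unexposed")
        km[[key]] <- weighted_km(tab[[cols[1]]], tab[[cols[2]]], grp,
                                 weights_store[[drug]])
        logrank[[key]] <- adjusted_logrank(tab[[cols[1]]], tab[[cols[2]]],
                                           grp, weights_store[[drug]],
                                           alpha = config$logrank_alpha)
      }
    }
  }

  out <- structure(list(results = results, balance = balance, pse = pse,
                        km = km, logrank = logrank,
                        eligible = drugs, config = config),
                   class = "screen_result")
  if (!is.null(out_dir)) write_screen_report(out, out_dir)
  out
}

# rbind data.frames with differing columns, filling with NA.
.rbind_fill <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  out <- do.call(rbind, lapply(lst, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.screen_result <- function(x, ...) {
  r <- x$results
  cat("<screen_result>", length(x$eligible), "drugs screened\n")
  if (nrow(r)) {
    cat("  gate passed:", sum(r$gate %in% TRUE) / length(unique(r$endpoint)),
        "drugs\n")
    if ("bh_reject" %in% names(r))
      cat("  BH-significant rows:", sum(r$bh_reject %in% TRUE), "\n")
  }
  invisible(x)
}
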