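# Path-specific effects through the ordered mediators (tumor subtype, then
# nodal status) by mediator-probability-ratio weighting on four
# counterfactual regimes.

PSE_PROB_FLOOR <- 1e-6

#' Fit the mediator models
#'
#' Multinomial logit of tumor subtype (4 levels, luminal reference) on
#' exposure and the pre-exposure covariates, and binomial logit of nodal
#' status on exposure, covariates and subtype. Fitted probabilities are
#' floored at 1e-6 (and renormalized for the subtype model).
#'
#' @param data analysis data.frame with columns `exposure`, `subtype`
#'   (factor with the four levels), `node` (0/1), and the covariates.
#' @param covariates character vector of covariate column names (default:
#'   the `"covariates"` attribute of `data`).
#' @return object of class `mediator_models`.
#' @export
fit_mediator_models <- function(data, covariates = attr(data, "covariates")) {
  if (is.null(covariates)) stop_pharmscreen("covariate names required")
  data$subtype <- droplevels(factor(data$subtype))
  if (nlevels(data$subtype) < 4 || any(table(data$subtype) == 0))
    stop_pharmscreen("missing mediator level: all four subtype levels must ",
                     "be present; collapse levels via config for smaller ",
                     "cohorts")
  if (length(unique(data$node)) < 2)
    stop_pharmscreen("missing mediator level: both nodal statuses must be present")
  f1 <- stats::reformulate(c("exposure", covariates), response = "subtype")
  m1 <- nnet::multinom(f1, data = data, trace = FALSE, maxit = 200)
  f2 <- stats::reformulate(c("exposure", covariates, "subtype"),
                           response = "node")
  # near-degenerate fits are handled by the probability floor downstream
  m2 <- suppressWarnings(
    stats::glm(f2, data = data, family = stats::binomial(),
               model = FALSE, y = FALSE))
  if (!is.finite(stats::logLik(m1)) || !is.finite(stats::logLik(m2)))
    stop_pharmscreen("mediator model log-likelihood not finite")
  structure(list(m1 = m1, m2 = m2, covariates = covariates),
            class = "mediator_models")
}

# P(M1 = level | A = a, C) for every patient: n x 4 matrix, floored and
# renormalized.
.m1_probs <- function(models, data, a) {
  nd <- data
  nd$exposure <- a
  p <- stats::predict(models$m1, newdata = nd, type = "probs")
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p <- pmax(p, PSE_PROB_FLOOR)
  p / rowSums(p)
}

# Probability of each patient's observed subtype under exposure setting a.
.m1_obs_prob <- function(models, data, a) {
  p <- .m1_probs(models, data, a)
  p[cbind(seq_len(nrow(data)), match(as.character(data$subtype), colnames(p)))]
}

# Probability of each patient's observed nodal status under exposure a
# (conditioning on the observed subtype).
.m2_obs_prob <- function(models, data, a) {
  nd <- data
  nd$exposure <- a
  p <- stats::predict(models$m2, newdata = nd, type = "response")
  p <- pmin(pmax(p, PSE_PROB_FLOOR), 1 - PSE_PROB_FLOOR)
  ifelse(data$node == 1, p, 1 - p)
}

#' Counterfactual-regime weights
#'
#' For regime `(a, a1, a2)` the estimator reweights the patients with
#' observed exposure `a`: the stabilized IPT weight is multiplied by the
#' mediator-probability ratios `P(M1 = m1_i | A = a1, C) / P(M1 = m1_i |
#' A = a, C)` and `P(M2 = m2_i | A = a2, C, m1_i) / P(M2 = m2_i | A = a, C,
#' m1_i)`. Ratios are identically 1 when the regime index equals `a`, so
#' regimes (1,1,1) and (0,0,0) carry plain stabilized IPTW. The
#' mediator-ratio product is capped at its `cap` quantile for variance
#' control (the cap therefore never alters a ratio-free regime).
#'
#' @param data analysis data.frame (as in [fit_mediator_models()]) with a
#'   `patient_id` column.
#' @param models a [fit_mediator_models()] object.
#' @param regime one of `"r000"`, `"r100"`, `"r101"`, `"r111"`, or a numeric
#'   triple `(a, a1, a2)`.
#' @param base_weights stabilized IPT weights for the full cohort.
#' @param cap quantile at which the mediator-ratio product is capped
#'   (default 0.99; `1` disables).
#' @return list with `index` (row indices of the regime's patients) and
#'   `weights`.
#' @export
regime_weights <- function(data, models, regime, base_weights, cap = 0.99) {
  if (is.character(regime)) {
    if (!regime %in% names(PSE_REGIMES)) stop_pharmscreen("unknown regime")
    regime <- PSE_REGIMES[[regime]]
  }
  a <- regime[1]; a1 <- regime[2]; a2 <- regime[3]
  idx <- which(data$exposure == a)
  sub <- data[idx, , drop = FALSE]
  ratio <- rep(1, length(idx))
  if (a1 != a)
    ratio <- ratio * .m1_obs_prob(models, sub, a1) /
      .m1_obs_prob(models, sub, a)
  if (a2 != a)
    ratio <- ratio * .m2_obs_prob(models, sub, a2) /
      .m2_obs_prob(models, sub, a)
  if (any(!is.finite(ratio)))
    stop_pharmscreen("mediator probability floor breached in regime weights")
  if (cap < 1 && length(ratio))
    ratio <- pmin(ratio, stats::quantile(ratio, cap, names = FALSE))
  list(index = idx, weights = base_weights[idx] * ratio)
}

new_pse_decomposition <- function(direct, node, subtype, se = NULL,
                                  drug = NA_character_,
                                  endpoint = NA_character_,
                                  epsilon = 0.01, converged = TRUE) {
  total <- direct + node + subtype
  stable <- is.finite(total) && abs(total) >= epsilon
  structure(list(drug = drug, endpoint = endpoint,
                 total = total,
                 pse_direct = direct, pse_node = node, pse_subtype = subtype,
                 pct_direct = 100 * direct / total,
                 pct_node = 100 * node / total,
                 pct_subtype = 100 * subtype / total,
                 se = se, stable = stable, converged = converged,
                 epsilon = epsilon),
            class = "pse_decomposition")
}

#' @export
print.pse_decomposition <- function(x, ...) {
  cat("<pse_decomposition>",
      if (!is.na(x$drug)) paste0(x$drug, " "),
      if (!is.na(x$endpoint)) x$endpoint, "\n",
      sprintf("  total log-HR %.4f (HR %.3f)%s\n", x$total, exp(x$total),
              if (!x$stable) " [unstable: |total| < epsilon]" else ""),
      sprintf("  direct  %.4f (%.1f%%)\n", x$pse_direct, x$pct_direct),
      sprintf("  node    %.4f (%.1f%%)\n", x$pse_node, x$pct_node),
      sprintf("  subtype %.4f (%.1f%%)\n", x$pse_subtype, x$pct_subtype),
      sep = "")
  invisible(x)
}

#' Path-specific effect decomposition
#'
#' Builds the four counterfactual pseudo-populations with [regime_weights()]
#' and fits a single weighted Cox model on the stacked data with nested
#' regime indicators, so that the three coefficients are the direct
#' (regime (1,0,0) vs (0,0,0)), node-path ((1,0,1) vs (1,0,0)) and
#' subtype-path ((1,1,1) vs (1,0,1)) log hazard ratios, and their sum is the
#' total effect by construction. The variance is a cluster-robust sandwich
#' over patients (each patient appears in two pseudo-populations, exposed
#' patients in three).
#'
#' @param data analysis data.frame with `patient_id`, `exposure`, mediators,
#'   outcome columns and covariates.
#' @param models a [fit_mediator_models()] object.
#' @param base_weights stabilized IPT weights.
#' @param time,event names of the outcome columns (default OS).
#' @param epsilon percentages are flagged unstable when |total log-HR| is
#'   below this (default 0.01).
#' @param cap cap quantile passed to [regime_weights()].
#' @param drug,endpoint labels carried into the result.
#' @return object of class `pse_decomposition`: total and component log-HRs,
#'   percentages of total, cluster-robust SEs, stability flag.
#' @export
path_specific_effects <- function(data, models, base_weights,
                                  time = "os_time", event = "os_event",
                                  epsilon = 0.01, cap = 0.99,
                                  drug = NA_character_, endpoint = "OS") {
  pieces <- lapply(seq_along(PSE_REGIMES), function(k) {
    rw <- regime_weights(data, models, names(PSE_REGIMES)[k], base_weights,
                         cap = cap)
    cbind(data.frame(t = data[[time]][rw$index],
                     e = data[[event]][rw$index],
                     id = data$patient_id[rw$index],
                     w = rw$weights, stringsAsFactors = FALSE),
          .regime_design(rep(k, length(rw$index))))
  })
  stacked <- do.call(rbind, pieces)
  stacked$w <- stacked$w / mean(stacked$w)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(t, e) ~ z_direct + z_node + z_subtype,
                    data = stacked, weights = stacked$w,
                    cluster = stacked$id, robust = TRUE, ties = "efron"),
    warning = function(cw) {
      if (grepl("converge|infinite|beta may be", conditionMessage(cw)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  new_pse_decomposition(direct = unname(b["z_direct"]),
                        node = unname(b["z_node"]),
                        subtype = unname(b["z_subtype"]),
                        se = sqrt(diag(fit$var)),
                        drug = drug, endpoint = endpoint,
                        epsilon = epsilon, converged = converged)
}

#' One-call path-specific effect estimation
#'
#' Convenience wrapper running the full chain on an analysis cohort:
#' propensity model, stabilized weights, mediator models, and the
#' decomposition.
#'
#' @inheritParams path_specific_effects
#' @param covariates covariate column names (default: `"covariates"`
#'   attribute of `data`).
#' @return a `pse_decomposition`.
#' @export
pse_estimate <- function(data, covariates = attr(data, "covariates"),
                         time = "os_time", event = "os_event",
                         epsilon = 0.01, cap = 0.99,
                         drug = NA_character_, endpoint = "OS") {
  ps <- estimate_propensity(data[covariates], data$exposure)
  sw <- stabilized_weights(ps, data$exposure)
  models <- fit_mediator_models(data, covariates)
  path_specific_effects(data, models, sw, time = time, event = event,
                        epsilon = epsilon, cap = cap, drug = drug,
                        endpoint = endpoint)
}

#' Bootstrap confidence intervals for the path-specific effects
#'
#' Nonparametric patient-level bootstrap of the full chain (propensity
#' model, stabilized weights, mediator models, decomposition). Replicates in
#' which a mediator level disappears are dropped and counted; a warning is
#' issued when more than 5% are dropped. Percentile intervals are returned
#' for each component and each percentage.
#'
#' @inheritParams pse_estimate
#' @param n_boot number of bootstrap replicates (at least 50).
#' @param seed integer seed; fixed seed gives identical intervals.
#' @param level confidence level (default 0.95).
#' @return list with `ci` (percentile intervals, rows = quantities), `se`
#'   (bootstrap standard errors), `replicates` (matrix of replicate
#'   estimates), `n_dropped`.
#' @export
pse_bootstrap_ci <- function(data, covariates = attr(data, "covariates"),
                             time = "os_time", event = "os_event",
                             n_boot = 200, seed = 1L, level = 0.95,
                             epsilon = 0.01, cap = 0.99) {
  if (n_boot < 50) stop_pharmscreen("n_boot must be at least 50")
  n <- nrow(data)
  qty <- c("pse_direct", "pse_node", "pse_subtype", "total",
           "pct_direct", "pct_node", "pct_subtype")
  reps <- matrix(NA_real_, n_boot, length(qty), dimnames = list(NULL, qty))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- sample.int(n, n, replace = TRUE)
      boot <- data[take, , drop = FALSE]
      boot$patient_id <- seq_len(n)  # resampled copies are distinct clusters
      attr(boot, "covariates") <- covariates
      est <- tryCatch(
        pse_estimate(boot, covariates, time = time, event = event,
                     epsilon = epsilon, cap = cap),
        error = function(e) NULL)
      if (!is.null(est))
        reps[b, ] <- unlist(est[qty])
    }
  })
  ok <- stats::complete.cases(reps)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.05 * n_boot)
    warning(n_dropped, " of ", n_boot,
            " bootstrap replicates dropped (degenerate resample)",
            call. = FALSE)
  keep <- reps[ok, , drop = FALSE]
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(keep, 2, stats::quantile, probs = pr, na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, se = apply(keep, 2, stats::sd),
       replicates = reps, n_dropped = n_dropped)
}
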