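# Average treatment effect: weighted Cox with robust inference, and the
# Benjamini-Hochberg screen across drugs.

#' Marginal hazard ratio by weighted Cox regression
#'
#' Fits a univariate Cox proportional-hazards model of the outcome on the
#' exposure in the weighted pseudo-population (Efron ties), with a robust
#' sandwich variance that treats the weights as fixed, and returns the
#' hazard ratio with two-sided Wald inference. Weights are normalized to
#' mean 1 internally; the estimate and robust p-value are invariant to
#' rescaling the weights.
#'
#' @param times follow-up times (months).
#' @param events 0/1 event indicators.
#' @param exposure 0/1 exposure vector.
#' @param weights positive case weights (default: unweighted).
#' @param endpoint label carried into the result ("OS" or "DFS").
#' @param drug drug label carried into the result.
#' @return one-row data.frame of class `ate_result`: `drug`, `endpoint`,
#'   `hr`, `log_hr`, `robust_se`, `ci_lower`, `ci_upper`, `p_value`,
#'   `n_exposed`, `n_unexposed`, `n_events`, `converged`.
#' @export
weighted_cox_ate <- function(times, events, exposure, weights = NULL,
                             endpoint = "OS", drug = NA_character_) {
  exposure <- as.integer(exposure)
  events <- as.integer(events)
  if (is.null(weights)) weights <- rep(1, length(times))
  if (any(weights <= 0)) stop_pharmscreen("weights must be positive")
  if (sum(events[exposure == 1]) < 1 || sum(events[exposure == 0]) < 1)
    stop_pharmscreen("need at least one event in each exposure group")
  w <- weights / mean(weights)
  dat <- data.frame(t = times, e = events, a = exposure, w = w)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(t, e) ~ a, data = dat, weights = w,
                    robust = TRUE, ties = "efron"),
    warning = function(cw) {
      if (grepl("converge|infinite|beta may be", conditionMessage(cw)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))  # robust variance when robust = TRUE
  if (!is.finite(b) || abs(b) > 15) converged <- FALSE
  z <- b / se
  out <- data.frame(
    drug = drug, endpoint = endpoint,
    hr = exp(b), log_hr = b, robust_se = se,
    ci_lower = exp(b - 1.96 * se), ci_upper = exp(b + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_exposed = sum(exposure == 1), n_unexposed = sum(exposure == 0),
    n_events = sum(events), converged = converged,
    stringsAsFactors = FALSE)
  class(out) <- c("ate_result", "data.frame")
  out
}

#' Benjamini-Hochberg screening across drugs
#'
#' Step-up false-discovery-rate control: adjusted p-values are the
#' monotonicity-enforced `m * p_(i) / i`, and a drug is rejected when its
#' adjusted p-value is at most `q`. Applied per endpoint across the
#' gate-passing drugs.
#'
#' @param pvalues raw p-values in \[0,1\].
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical flags at level `q`).
#' @export
benjamini_hochberg <- function(pvalues, q = 0.05) {
  if (length(pvalues) && (any(pvalues < 0) || any(pvalues > 1)))
    stop_pharmscreen("p-values must lie in [0,1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}
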