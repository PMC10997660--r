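# Propensity scores, stabilized IPT weights, covariate balance and the
# adjustment-quality gate.

#' Estimate propensity scores
#'
#' Main-effects logistic regression of the exposure on the pre-exposure
#' covariates; returns the fitted probability of exposure for every patient.
#' Zero-variance covariates are dropped from the model (they carry no
#' confounding information). Degenerate exposure and (quasi-)complete
#' separation are errors, the latter naming the offending covariate.
#'
#' @param covariates data.frame or matrix of pre-exposure covariates (no
#'   missing values).
#' @param exposure 0/1 (or logical) exposure vector.
#' @return numeric vector of propensity scores in (0,1), with the fitted
#'   coefficients in attribute `"coefficients"`.
#' @export
estimate_propensity <- function(covariates, exposure) {
  exposure <- as.integer(exposure)
  if (length(unique(exposure)) < 2)
    stop_pharmscreen("degenerate exposure: all patients in one group")
  X <- as.data.frame(covariates)
  keep <- vapply(X, function(col) length(unique(col)) > 1, logical(1))
  X <- X[, keep, drop = FALSE]
  dat <- cbind(.y = exposure, X)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               model = FALSE, y = FALSE))
  cf <- stats::coef(fit)
  big <- !is.na(cf) & abs(cf) > 20
  big[1] <- FALSE  # intercept scale is legitimate
  if (!fit$converged || any(big)) {
    culprit <- if (any(big)) names(cf)[big][1] else "unknown"
    stop_pharmscreen("perfect separation suspected for covariate ", culprit)
  }
  ps <- stats::fitted(fit)
  ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
  attr(ps, "coefficients") <- cf
  ps
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `w_i = A_i * pbar / PS_i + (1 - A_i) * (1 - pbar) / (1 - PS_i)`, where
#' `pbar` is the marginal exposure rate. Stabilization keeps the mean weight
#' near 1 and reduces variance relative to plain inverse weighting.
#'
#' @param ps propensity scores, strictly inside (0,1).
#' @param exposure 0/1 exposure vector.
#' @return positive weight vector.
#' @export
stabilized_weights <- function(ps, exposure) {
  exposure <- as.integer(exposure)
  if (any(ps <= 0 | ps >= 1))
    stop_pharmscreen("propensity scores at 0 or 1: separation upstream")
  pbar <- mean(exposure)
  exposure * pbar / ps + (1 - exposure) * (1 - pbar) / (1 - ps)
}

#' Weighted standardized mean difference
#'
#' Difference in weighted group means divided by the pooled standard
#' deviation, `(m1 - m0) / sqrt((s1^2 + s0^2)/2)`, with weighted variances.
#' Binary covariates use the proportion variance `p(1-p)`; continuous
#' covariates use the reliability-weighted sample variance, which reduces to
#' the usual n-1 sample variance at unit weights. A zero pooled variance
#' with unequal means is reported as signed infinity (which fails the gate).
#'
#' @param values numeric covariate vector (0/1 for binary covariates).
#' @param exposure 0/1 exposure vector.
#' @param weights positive weights (default: unweighted).
#' @return signed SMD (exposed minus unexposed).
#' @export
weighted_smd <- function(values, exposure, weights = NULL) {
  exposure <- as.integer(exposure)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (!any(exposure == 1) || !any(exposure == 0))
    stop_pharmscreen("both exposure groups must be non-empty")
  values <- as.numeric(values)
  grp <- function(g) {
    w <- weights[exposure == g]; x <- values[exposure == g]
    sw <- sum(w)
    if (sw <= 0) stop_pharmscreen("non-positive total weight in a group")
    m <- sum(w * x) / sw
    v <- if (all(values %in% c(0, 1))) m * (1 - m)
         else sum(w * (x - m)^2) * sw / (sw^2 - sum(w^2))
    c(m, v)
  }
  g1 <- grp(1L); g0 <- grp(0L)
  denom <- sqrt((g1[2] + g0[2]) / 2)
  diff <- g1[1] - g0[1]
  if (denom == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / denom
}

#' Covariate balance report after weighting
#'
#' Weighted SMD for every covariate, with the maximum absolute SMD and the
#' gate decision attached.
#'
#' @param covariates data.frame or matrix of pre-exposure covariates.
#' @param exposure 0/1 exposure vector.
#' @param weights weights (default unweighted: raw imbalance).
#' @param threshold gate threshold on |SMD| (default 0.1).
#' @return data.frame of class `balance_report` (`covariate`, `smd`) with
#'   attributes `max_abs_smd` and `pass`.
#' @export
balance_report <- function(covariates, exposure, weights = NULL,
                           threshold = 0.1) {
  X <- as.data.frame(covariates)
  if (ncol(X) == 0) stop_pharmscreen("balance report needs >= 1 covariate")
  smd <- vapply(X, function(col) weighted_smd(col, exposure, weights),
                numeric(1))
  out <- data.frame(covariate = names(X), smd = unname(smd),
                    stringsAsFactors = FALSE)
  class(out) <- c("balance_report", "data.frame")
  attr(out, "max_abs_smd") <- max(abs(out$smd))
  attr(out, "pass") <- quality_gate(out, threshold)
  out
}

#' Adjustment-quality gate
#'
#' The adjustment is judged insufficient — and the drug excluded from the
#' downstream steps — when any covariate has |SMD| strictly above the
#' threshold. An SMD exactly at the threshold passes.
#'
#' @param balance a [balance_report()] (or data.frame with an `smd` column).
#' @param threshold gate threshold (default 0.1).
#' @return logical: `TRUE` when the adjustment passes.
#' @export
quality_gate <- function(balance, threshold = 0.1) {
  if (nrow(balance) == 0) stop_pharmscreen("empty balance report")
  !any(abs(balance$smd) > threshold)
}
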