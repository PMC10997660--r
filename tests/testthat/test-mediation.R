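# Mediator models, regime weights and the path-specific decomposition.

test_that("mediator models recover generating exposure coefficients", {
  # null coupling: exposure coefficients near zero
  ac <- truth_cohort(scenario_config("null", n_patients = 20000, seed = 51))
  m <- fit_mediator_models(ac)
  cf1 <- summary(m$m1)$coefficients[, "exposure"]
  se1 <- summary(m$m1)$standard.errors[, "exposure"]
  expect_true(all(abs(cf1) < 3 * se1 + 1e-8))
  cf2 <- summary(m$m2)$coefficients["exposure", ]
  expect_lt(abs(cf2[["Estimate"]]), 3 * cf2[["Std. Error"]])

  # node coupling log(3): recovered within 3 SE
  acn <- truth_cohort(scenario_config("node", n_patients = 20000, seed = 52))
  mn <- fit_mediator_models(acn)
  cfn <- summary(mn$m2)$coefficients["exposure", ]
  expect_lt(abs(cfn[["Estimate"]] - log(3)), 3 * cfn[["Std. Error"]])
})

test_that("a missing mediator level is an instructive error", {
  ac <- truth_cohort(small_config(n = 2000, seed = 53))
  no_tnbc <- ac[ac$subtype != "tnbc", ]
  attr(no_tnbc, "covariates") <- attr(ac, "covariates")
  expect_error(fit_mediator_models(no_tnbc), "collapse levels")
})

test_that("ratio-free regimes carry plain stabilized IPTW", {
  ac <- truth_cohort(small_config(n = 4000, seed = 54))
  covs <- attr(ac, "covariates")
  sw <- stabilized_weights(estimate_propensity(ac[covs], ac$exposure),
                           ac$exposure)
  m <- fit_mediator_models(ac)
  r111 <- regime_weights(ac, m, "r111", sw)
  expect_equal(r111$index, which(ac$exposure == 1))
  expect_equal(r111$weights, sw[ac$exposure == 1], tolerance = 1e-12)
  r000 <- regime_weights(ac, m, "r000", sw)
  expect_equal(r000$weights, sw[ac$exposure == 0], tolerance = 1e-12)
})

test_that("regime (1,0,0) weights approach IPTW when mediation is absent", {
  ac <- truth_cohort(scenario_config("null", n_patients = 20000, seed = 55))
  covs <- attr(ac, "covariates")
  sw <- stabilized_weights(estimate_propensity(ac[covs], ac$exposure),
                           ac$exposure)
  m <- fit_mediator_models(ac)
  r100 <- regime_weights(ac, m, "r100", sw, cap = 1)
  lr <- log(r100$weights / sw[r100$index])
  expect_lt(mean(abs(lr)), 0.1)  # ratio terms -> 1
})

test_that("decomposition telescopes and matches the two-group ATE", {
  ac <- truth_cohort(small_config(n = 6000, seed = 56))
  covs <- attr(ac, "covariates")
  sw <- stabilized_weights(estimate_propensity(ac[covs], ac$exposure),
                           ac$exposure)
  m <- fit_mediator_models(ac)
  dec <- path_specific_effects(ac, m, sw)
  expect_lt(abs(dec$pse_direct + dec$pse_node + dec$pse_subtype - dec$total),
            1e-10)
  expect_equal(dec$pct_direct + dec$pct_node + dec$pct_subtype, 100,
               tolerance = 1e-8)
  # the stacked r111 + r000 sub-population is exactly the ATE's weighted data
  ate <- weighted_cox_ate(ac$os_time, ac$os_event, ac$exposure, sw)
  r111 <- regime_weights(ac, m, "r111", sw)
  r000 <- regime_weights(ac, m, "r000", sw)
  idx <- c(r000$index, r111$index)
  two <- weighted_cox_ate(ac$os_time[idx], ac$os_event[idx],
                          ac$exposure[idx], c(r000$weights, r111$weights))
  expect_equal(two$log_hr, ate$log_hr, tolerance = 1e-8)
})

test_that("absent mediated paths put all of the effect on the direct path", {
  ac <- truth_cohort(scenario_config("direct", n_patients = 20000, seed = 57))
  dec <- pse_estimate(ac)
  expect_true(dec$stable)
  expect_lt(abs(dec$pct_direct - 100), 10)
  # mediated components are null up to mediator-model estimation noise
  # (plug-in robust SEs hold the mediator models fixed, so compare on an
  # absolute scale small relative to the total effect ~ -0.32)
  expect_lt(abs(dec$pse_node), 0.03)
  expect_lt(abs(dec$pse_subtype), 0.03)
})

test_that("bootstrap intervals are deterministic and flag degenerate resamples", {
  ac <- truth_cohort(small_config(n = 400, seed = 58))
  b1 <- pse_bootstrap_ci(ac, n_boot = 50, seed = 7)
  b2 <- pse_bootstrap_ci(ac, n_boot = 50, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  expect_error(pse_bootstrap_ci(ac, n_boot = 10, seed = 7), "at least 50")
  # a tiny cohort drops many replicates and warns
  tiny <- truth_cohort(small_config(n = 60, seed = 59))
  expect_warning(pse_bootstrap_ci(tiny, n_boot = 50, seed = 7),
                 "replicates dropped")
})
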