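# Synthetic claims generator: schema, determinism, calibration against the
# structural model.

test_that("empty cohort yields valid empty tables", {
  ds <- generate_cohort(cohort_config(n_patients = 0))
  expect_s3_class(ds, "claims_dataset")
  for (nm in c("patients", "dispensings", "code_events", "care_events",
               "tumors", "truth"))
    expect_equal(nrow(ds[[nm]]), 0)
  expect_true(all(c("patient_id", "index_date", "age") %in%
                    names(ds$patients)))
  expect_true(all(c("patient_id", "date", "atc_code", "packs",
                    "units_per_pack", "daily_dose") %in%
                    names(ds$dispensings)))
})

test_that("identical config and seed reproduce every table bit-identically", {
  cfg <- small_config(n = 3000, seed = 42)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1$patients, d2$patients)
  expect_identical(d1$dispensings, d2$dispensings)
  expect_identical(d1$code_events, d2$code_events)
  expect_identical(d1$care_events, d2$care_events)
  expect_identical(d1$tumors, d2$tumors)
  expect_identical(d1$truth, d2$truth)
  # patient-level draws do not depend on the claims-detail layer
  d3 <- generate_cohort(cfg, detail = "cohort")
  expect_identical(d1$patients, d3$patients)
  expect_identical(d1$truth, d3$truth)
})

test_that("tables are referentially consistent", {
  ds <- generate_cohort(small_config(n = 1500, seed = 3))
  for (nm in c("dispensings", "code_events", "care_events", "tumors",
               "truth"))
    expect_true(all(ds[[nm]]$patient_id %in% ds$patients$patient_id))
  expect_equal(nrow(ds$tumors), nrow(ds$patients))
  expect_false(anyDuplicated(ds$tumors$patient_id) > 0)
  expect_true(all(ds$truth$true_event_time >= 0))
  expect_true(all(ds$truth$true_censor_time >= 0))
})

test_that("exposure prevalence matches the analytic mean over the covariate law", {
  cfg <- small_config(n = 20000, seed = 10)
  ds <- generate_cohort(cfg, detail = "cohort")
  # large-sample oracle: average expit(alpha . C) over an independent draw
  # of the covariate law
  big <- truth_cohort(small_config(n = 200000, seed = 999))
  X <- as.matrix(big[, attr(big, "covariates")])
  p_oracle <- mean(expit_for_test(cfg$alpha[1] + X %*% cfg$alpha[-1]))
  p_hat <- mean(ds$truth$true_exposure)
  se <- sqrt(p_oracle * (1 - p_oracle) / cfg$n_patients)
  expect_lt(abs(p_hat - p_oracle), 3 * se)
})

test_that("subtype and nodal frequencies match configured baselines", {
  cfg <- small_config(n = 20000, seed = 8)
  ds <- generate_cohort(cfg, detail = "cohort")
  freq <- table(ds$tumors$subtype) / nrow(ds$tumors)
  for (lev in names(cfg$subtype_baseline)) {
    p <- cfg$subtype_baseline[[lev]]
    expect_lt(abs(freq[[lev]] - p), 3 * sqrt(p * (1 - p) / 20000))
  }
  p <- cfg$node_baseline
  expect_lt(abs(mean(ds$tumors$node_positive) - p),
            3 * sqrt(p * (1 - p) / 20000))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = -1), "non-negative")
  expect_error(cohort_config(weibull_shape = 0), "positive")
  expect_error(cohort_config(subtype_baseline = c(luminal = 0.5, tnbc = 0.2,
                                                  her2 = 0.2,
                                                  undefined = 0.2)),
               "sum to 1")
  expect_error(cohort_config(node_baseline = 1.2), "node_baseline")
  cfg <- small_config(n = 10)
  cfg$alpha["age_z"] <- Inf
  suppressWarnings(expect_error(generate_cohort(cfg), "rejecting config"))
})
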