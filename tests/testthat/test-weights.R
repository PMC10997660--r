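# Propensity scores, stabilized weights, SMD and the balance gate.

test_that("intercept-only propensity model returns the exposure rate", {
  set.seed(4)
  n <- 10000
  a <- rbinom(n, 1, 0.3)
  ps <- estimate_propensity(data.frame(x = rep(1, n)), a)
  expect_equal(unname(ps[1]), mean(a), tolerance = 1e-8)
  expect_true(all(abs(ps - mean(a)) < 1e-8))
})

test_that("propensity model recovers generating coefficients", {
  set.seed(9)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, expit_for_test(-1 + x))
  ps <- estimate_propensity(data.frame(x = x), a)
  cf <- attr(ps, "coefficients")
  expect_lt(abs(cf[["(Intercept)"]] - (-1)), 0.1)  # ~3 SE at this n
  expect_lt(abs(cf[["x"]] - 1), 0.12)
})

test_that("degenerate exposure and separation are errors", {
  expect_error(estimate_propensity(data.frame(x = 1:10), rep(1, 10)),
               "degenerate exposure")
  sep <- data.frame(x = c(rep(0, 50), rep(1, 50)))
  expect_error(estimate_propensity(sep, sep$x), "separation.*x")
})

test_that("stabilized weight arithmetic matches the closed form", {
  expect_equal(stabilized_weights(rep(0.5, 4), c(1, 1, 0, 0)), rep(1, 4))
  expect_equal(stabilized_weights(c(0.25, 0.25), c(1, 0)),
               c(0.5 / 0.25, 0.5 / 0.75))
  expect_error(stabilized_weights(c(0, 0.5), c(1, 0)), "separation")
})

test_that("mean stabilized weight stays near one across seeds", {
  devs <- vapply(1:20, function(s) {
    ac <- truth_cohort(small_config(n = 5000, seed = 400 + s))
    ps <- estimate_propensity(ac[attr(ac, "covariates")], ac$exposure)
    abs(mean(stabilized_weights(ps, ac$exposure)) - 1)
  }, numeric(1))
  expect_true(all(devs < 0.02))
})

test_that("weighted SMD reproduces hand computations", {
  x <- c(1, 2, 3, 2, 3, 4)
  a <- c(1, 1, 1, 0, 0, 0)
  expect_equal(weighted_smd(x, a), -1.0, tolerance = 1e-12)
  # binary proportions 0.5 vs 0.3 -> 0.2 / sqrt((0.25 + 0.21)/2)
  xb <- c(rep(1, 5), rep(0, 5), rep(1, 3), rep(0, 7))
  ab <- rep(c(1, 0), each = 10)
  expect_equal(weighted_smd(xb, ab), 0.2 / sqrt(0.23), tolerance = 1e-12)
  # identical weighted distributions -> 0
  expect_equal(weighted_smd(c(1, 2, 1, 2), c(1, 1, 0, 0)), 0)
  # degenerate: zero variance with unequal means -> signed infinity
  expect_equal(weighted_smd(c(2, 2, 1, 1), c(1, 1, 0, 0)), Inf)
  # weights matter: downweighting removes the difference
  sm_w <- weighted_smd(c(1, 5, 1, 5), c(1, 1, 0, 0),
                       weights = c(1, 1e-9, 1, 1e-9))
  expect_lt(abs(sm_w), 1e-6)
})

test_that("the balance gate is strict only above the threshold", {
  rep1 <- data.frame(covariate = c("a", "b"), smd = c(0.05, -0.09))
  expect_true(quality_gate(rep1))
  rep2 <- data.frame(covariate = c("a", "b"), smd = c(0.05, 0.11))
  expect_false(quality_gate(rep2))
  rep3 <- data.frame(covariate = "a", smd = 0.10)
  expect_true(quality_gate(rep3))  # "above 0.1" is strict
  expect_error(quality_gate(rep3[0, ]), "empty")
})

test_that("balance_report flags the strong confounder left out of the PS model", {
  ac <- truth_cohort(small_config(n = 20000, seed = 12))
  covs <- attr(ac, "covariates")
  ps <- estimate_propensity(ac[covs], ac$exposure)
  sw <- stabilized_weights(ps, ac$exposure)
  full <- balance_report(ac[covs], ac$exposure, sw)
  expect_true(attr(full, "pass"))
  ps2 <- estimate_propensity(ac[setdiff(covs, "age_z")], ac$exposure)
  sw2 <- stabilized_weights(ps2, ac$exposure)
  part <- balance_report(ac[covs], ac$exposure, sw2)
  expect_false(attr(part, "pass"))
  expect_gt(abs(part$smd[part$covariate == "age_z"]), 0.1)
})
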