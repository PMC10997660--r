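# Chronic-exposure coding, combination splitting, medication filtering.

idx <- as.Date("2015-06-01")

test_that("three monthly packs reaching 90 covered days code as chronic", {
  disp <- rbind(make_disp(150), make_disp(120), make_disp(90))
  expect_true(code_chronic_exposure(disp, idx, "A01AA01"))
})

test_that("empty, short or post-index dispensing streams code as non-chronic", {
  expect_false(code_chronic_exposure(make_disp(30)[0, ], idx, "A01AA01"))
  expect_false(code_chronic_exposure(make_disp(30), idx, "A01AA01"))
  # a pack dispensed after the index date contributes nothing
  disp <- rbind(make_disp(30), make_disp(-10))
  expect_false(code_chronic_exposure(disp, idx, "A01AA01"))
  # the index date itself is outside the window
  expect_false(code_chronic_exposure(make_disp(0), idx, "A01AA01"))
})

test_that("exposure coding respects dose rules and the window cap", {
  disp <- rbind(make_disp(150), make_disp(120), make_disp(90))
  rules2 <- exposure_rules(dose_rules = list(A01AA01 = 2))  # 2 units/day
  expect_false(code_chronic_exposure(disp, idx, "A01AA01", rules2))
  # massive stockpiling is capped at the window length, still chronic
  big <- make_disp(100, packs = 50)
  expect_true(code_chronic_exposure(big, idx, "A01AA01"))
})

test_that("exposure coding is invariant to row order and pack splitting", {
  disp <- rbind(make_disp(150), make_disp(120), make_disp(90))
  expect_identical(code_chronic_exposure(disp, idx, "A01AA01"),
                   code_chronic_exposure(disp[3:1, ], idx, "A01AA01"))
  halves <- rbind(make_disp(150, units = 15), make_disp(150, units = 15),
                  make_disp(120), make_disp(90))
  expect_identical(code_chronic_exposure(disp, idx, "A01AA01"),
                   code_chronic_exposure(halves, idx, "A01AA01"))
})

test_that("invalid dispensing rows are dropped with a warning", {
  disp <- rbind(make_disp(150), make_disp(120, packs = -1), make_disp(90))
  expect_warning(out <- code_chronic_exposure(disp, idx, "A01AA01"),
                 "non-positive")
  expect_false(out)  # only 60 valid covered days
})

test_that("combination dispensings split into components", {
  cmap <- list(C07BB02 = c("C07AB02", "C03AA03"))
  one <- make_disp(100, atc = "C07BB02")
  out <- split_combinations(one, cmap)
  expect_equal(nrow(out), 2)
  expect_setequal(out$atc_code, c("C07AB02", "C03AA03"))
  expect_equal(unique(out$date), one$date)

  expect_identical(split_combinations(one, list()), one)

  four <- one[rep(1, 4), ]
  out3 <- split_combinations(four, list(C07BB02 = c("A", "B", "C")))
  expect_equal(nrow(out3), 12)

  expect_error(split_combinations(one, list(C07BB02 = character(0))),
               "non-empty")
})

test_that("medication filter applies the exposed-count threshold and exclusions", {
  counts <- c(A01AA01 = 300, B01AA02 = 299)
  expect_equal(filter_medications(counts), "A01AA01")
  expect_equal(filter_medications(stats::setNames(integer(0), character(0))),
               character(0))
  expect_equal(filter_medications(c(V04CA01 = 1000)), character(0))
  expect_error(filter_medications(c(A01AA01 = -2)), "non-negative")
})

test_that("exposure coder recovers the generator's true exposure", {
  ds <- generate_cohort(small_config(n = 3000, seed = 17))
  expo <- build_exposure_table(ds)
  acc <- mean(expo$flags[, ds$config$index_atc] == ds$truth$true_exposure)
  expect_gte(acc, 0.99)  # exact recovery expected at zero adherence noise
  expect_equal(unname(expo$med_count), unname(rowSums(expo$flags)))
})
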