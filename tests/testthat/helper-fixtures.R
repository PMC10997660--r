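# Shared fixtures for the test suite. Everything is generated in code;
# small_* helpers keep the unit tests fast.

expit_for_test <- function(x) 1 / (1 + exp(-x))

small_config <- function(n = 2000, seed = 1L, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

# Analysis cohort straight from the generator's truth tables.
truth_cohort <- function(config) {
  analysis_cohort_from_truth(generate_cohort(config, detail = "cohort"))
}

# Tiny dispensing table builder (index date minus `days_before`).
make_disp <- function(days_before, atc = "A01AA01", packs = 1,
                      units = 30, index = as.Date("2015-06-01")) {
  data.frame(patient_id = "P1", date = index - days_before, atc_code = atc,
             packs = packs, units_per_pack = units, daily_dose = 1,
             stringsAsFactors = FALSE)
}

# Random small survival dataset for the unit-weight reduction checks.
random_surv_data <- function(n = 40) {
  data.frame(time = round(rexp(n, 0.1), 1) + 0.5,
             event = rbinom(n, 1, 0.7),
             group = sample(c("a", "b"), n, replace = TRUE,
                            prob = c(0.5, 0.5)))
}
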