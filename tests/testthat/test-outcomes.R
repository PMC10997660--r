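# Comorbidity ascertainment windows, OS and DFS construction.

mk_codes <- function(offsets, codes = "DX_METAB", source = "diagnosis",
                     index = as.Date("2015-06-01")) {
  data.frame(patient_id = "P1", date = index + offsets, code = codes,
             source = source, stringsAsFactors = FALSE)
}

test_that("diagnosis and procedure windows follow the primary timeframe", {
  index <- as.Date("2015-06-01"); surgery <- index + 30
  expect_equal(detect_comorbidities(mk_codes(100), index, surgery),
               "metabolic")
  expect_equal(detect_comorbidities(mk_codes(200), index, surgery),
               character(0))
  expect_equal(detect_comorbidities(mk_codes(10, source = "procedure"),
                                    index, surgery),
               character(0))  # procedures end at diagnosis
  expect_equal(detect_comorbidities(mk_codes(-10, source = "procedure"),
                                    index, surgery),
               "metabolic")
  # unmapped codes are ignored, never an error
  expect_equal(detect_comorbidities(mk_codes(0, codes = "DX_XYZ"), index,
                                    surgery),
               character(0))
})

test_that("sensitivity timeframes shift the diagnosis window", {
  index <- as.Date("2015-06-01")
  # sensitivity_a equals primary exactly when surgery = index + 180
  for (off in c(-300, -10, 50, 179, 181, 250)) {
    expect_identical(
      detect_comorbidities(mk_codes(off), index, index + 180, timeframe = "primary"),
      detect_comorbidities(mk_codes(off), index, index + 180, timeframe = "sensitivity_a"))
  }
  # sensitivity_b anchors the year to surgery
  surgery <- index + 30
  expect_equal(detect_comorbidities(mk_codes(-350), index, surgery,
                                    timeframe = "sensitivity_b"),
               character(0))  # before surgery - 365
  expect_equal(detect_comorbidities(mk_codes(20), index, surgery,
                                    timeframe = "sensitivity_b"),
               "metabolic")
})

test_that("overall survival follows the cutoff convention", {
  os <- compute_os(as.Date("2012-01-01"), as.Date("2012-07-01"))
  expect_equal(os$os_time, 182 / 30.44, tolerance = 1e-10)
  expect_equal(os$os_event, 1L)
  alive <- compute_os(as.Date("2018-03-01"), as.Date(NA))
  expect_equal(alive$os_time, 365 / 30.44, tolerance = 1e-10)
  expect_equal(alive$os_event, 0L)
  late <- compute_os(as.Date("2018-03-01"), as.Date("2019-06-01"))
  expect_equal(late$os_event, 0L)
  expect_equal(late$os_time, alive$os_time)
  expect_error(compute_os(as.Date("2012-01-01"), as.Date("2011-01-01")),
               "death before surgery")
})

test_that("DFS recurrence rules fire at the right anchors", {
  surgery <- as.Date("2015-01-01")
  tx_end <- surgery + 150
  mk_care <- function(kind, date) data.frame(patient_id = "P1", date = date,
                                             kind = kind, detail = "",
                                             stringsAsFactors = FALSE)
  # rule i: resumption 7 months after treatment end -> event
  seven <- tx_end + round(7 * 30.44)
  out <- derive_dfs(mk_care("chemo_start", seven), surgery, tx_end)
  expect_equal(out$dfs_event, 1L)
  expect_equal(out$recurrence_reason, "treatment_resumption")
  expect_equal(out$dfs_time, as.numeric(seven - surgery) / 30.44,
               tolerance = 1e-10)
  # 5 months after treatment end -> not an event
  five <- tx_end + round(5 * 30.44)
  out5 <- derive_dfs(mk_care("chemo_start", five), surgery, tx_end)
  expect_equal(out5$dfs_event, 0L)
  expect_equal(out5$recurrence_reason, "none")
  # rule ii needs a same-day axillary procedure
  bs <- tx_end + 200
  no_ax <- derive_dfs(mk_care("breast_surgery", bs), surgery, tx_end)
  expect_equal(no_ax$dfs_event, 0L)
  with_ax <- derive_dfs(rbind(mk_care("breast_surgery", bs),
                              mk_care("axillary_procedure", bs)),
                        surgery, tx_end)
  expect_equal(with_ax$recurrence_reason, "surgery_with_axillary")
  # rules iii/iv anchor to surgery + 6 months
  expect_equal(derive_dfs(mk_care("metastatic_drug", surgery + 190),
                          surgery, tx_end)$recurrence_reason,
               "metastatic_drug")
  expect_equal(derive_dfs(mk_care("metastatic_drug", surgery + 150),
                          surgery, tx_end)$dfs_event, 0L)
  expect_equal(derive_dfs(mk_care("metastasis_code", surgery + 190),
                          surgery, tx_end)$recurrence_reason,
               "metastasis_code")
  # ties between rules break in rule order (i before iv)
  tie_date <- tx_end + 190
  tie <- derive_dfs(rbind(mk_care("metastasis_code", tie_date),
                          mk_care("chemo_start", tie_date)),
                    surgery, tx_end)
  expect_equal(tie$recurrence_reason, "treatment_resumption")
})

test_that("death and censoring complete the DFS definition", {
  surgery <- as.Date("2015-01-01")
  empty_ce <- data.frame(patient_id = character(0),
                         date = as.Date(character(0)),
                         kind = character(0), detail = character(0))
  none <- derive_dfs(empty_ce, surgery, surgery)
  expect_equal(none$dfs_event, 0L)
  expect_equal(none$dfs_time,
               as.numeric(as.Date("2018-12-30") - surgery) / 30.44,
               tolerance = 1e-10)
  died <- derive_dfs(empty_ce, surgery, surgery,
                     death_date = as.Date("2016-01-01"))
  expect_equal(died$dfs_event, 1L)
  expect_equal(died$recurrence_reason, "death")
})

test_that("bulk DFS agrees with the per-patient rule application", {
  ds <- generate_cohort(small_config(n = 800, seed = 23))
  frame <- build_cohort_frame(ds, min_exposed = 50)
  base <- frame$base
  surgery <- ds$patients$index_date + ds$config$surgery_gap_days
  take <- sample(seq_len(nrow(base)), 60)
  for (i in take) {
    pid <- base$patient_id[i]
    ce <- ds$care_events[ds$care_events$patient_id == pid, , drop = FALSE]
    d <- as.Date(ce$date)
    ends <- d[ce$kind %in% c("chemo_end", "radiotherapy_end") &
                d >= surgery[i] & d <= surgery[i] + 365]
    tx_end <- if (length(ends)) max(max(ends), surgery[i]) else surgery[i]
    ref <- derive_dfs(ce, surgery[i], tx_end,
                      death_date = ds$patients$death_date[i])
    expect_equal(base$dfs_time[i], ref$dfs_time, tolerance = 1e-10)
    expect_equal(base$dfs_event[i], ref$dfs_event)
    expect_equal(base$recurrence_reason[i], ref$recurrence_reason)
  }
  # when death is the DFS event, recurrence-free time never exceeds OS time
  dd <- base$dfs_event == 1 & base$recurrence_reason == "death"
  expect_true(all(base$dfs_time[dd] <= base$os_time[dd] + 1e-8))
})
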