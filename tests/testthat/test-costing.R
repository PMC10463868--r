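# Bottom-up costing: currency conversion, human-capital valuation,
# aggregation invariants, and the whole-dollar reporting convention.

printed_imrt_means <- c(visits = 44.17, laboratory = 138.99,
                        diagnosis = 184.75, radiotherapy = 12995.65)
printed_crt_nonmed <- c(transport = 24.89, lodging = 55.83)

one_patient_items <- function(means, id = "p1") {
  tibble::tibble(patient_id = id, category = names(means),
                 amount = unname(means), currency = "USD")
}

test_that("IRR to USD conversion is linear with the study-period rate", {
  expect_equal(convert_to_usd(36692, 36692), 1.00)
  expect_equal(convert_to_usd(0, 36692), 0)
  expect_equal(convert_to_usd(91730, 36692), 2.50)
  # round trip within 1e-9 relative error
  x <- c(1, 17.57, 12995.65)
  expect_equal(convert_to_usd(x * 36692, 36692), x, tolerance = 1e-9)
  expect_error(convert_to_usd(-1), class = "radcea_invalid_input")
  expect_error(convert_to_usd(10, 0), class = "radcea_invalid_input")
})

test_that("human-capital indirect cost sums days times wages", {
  zero <- tibble::tibble(patient_days = 0, patient_wage = 0,
                         companion_days = 0, companion_wage = 0,
                         nursing_days = 0, nursing_rate = 0)
  expect_equal(indirect_cost_human_capital(zero), 0)
  expect_equal(indirect_cost_human_capital(
    dplyr::mutate(zero, patient_days = 30, patient_wage = 10)), 300)
  expect_equal(indirect_cost_human_capital(
    tibble::tibble(patient_days = 10, patient_wage = 12,
                   companion_days = 5, companion_wage = 8,
                   nursing_days = 2, nursing_rate = 20)), 200)
  expect_error(indirect_cost_human_capital(
    dplyr::mutate(zero, patient_days = -1)), class = "radcea_invalid_input")
})

test_that("aggregation reproduces printed group subtotals from category means", {
  bd <- aggregate_costs(one_patient_items(printed_imrt_means))
  expect_equal(bd$direct_medical_total, 13363.56, tolerance = 1e-9)
  bd2 <- aggregate_costs(one_patient_items(printed_crt_nonmed))
  expect_equal(bd2$direct_non_medical_total, 80.72, tolerance = 1e-9)
  # singleton: one item, everything else zero
  bd3 <- aggregate_costs(one_patient_items(c(visits = 5)))
  expect_equal(bd3$grand_total, 5)
  expect_equal(bd3$indirect_total, 0)
  expect_equal(bd3$n_patients, 1)
})

test_that("aggregation is permutation- and split-invariant and conserves totals", {
  set.seed(11)
  items <- tibble::tibble(
    patient_id = sample(c("a", "b", "c"), 40, replace = TRUE),
    category = sample(cost_categories(), 40, replace = TRUE),
    amount = stats::runif(40, 0, 500),
    currency = sample(c("USD", "IRR"), 40, replace = TRUE)
  )
  base <- aggregate_costs(items)
  perm <- aggregate_costs(items[sample(nrow(items)), ])
  expect_identical(glance(base), glance(perm))
  # split the first item in two halves of the same category
  split <- dplyr::bind_rows(
    items[-1, ],
    dplyr::mutate(items[1, ], amount = amount * 0.3),
    dplyr::mutate(items[1, ], amount = amount * 0.7)
  )
  expect_equal(glance(aggregate_costs(split)), glance(base), tolerance = 1e-9)
  # conservation: group totals reconstruct the grand total exactly as stored
  expect_identical(base$grand_total,
                   sum(base$per_category$mean_per_patient))
  expect_equal(base$direct_medical_total + base$direct_non_medical_total +
                 base$indirect_total, base$grand_total, tolerance = 1e-12)
})

test_that("aggregation converts IRR at ingestion and pools absenteeism", {
  items <- tibble::tibble(patient_id = c("a", "b"), category = "visits",
                          amount = c(36692, 2), currency = c("IRR", "USD"))
  absentee <- tibble::tibble(patient_id = c("a", "b"),
                             patient_days = c(10, 0), patient_wage = c(12, 0),
                             companion_days = 0, companion_wage = 0,
                             nursing_days = c(0, 2), nursing_rate = c(0, 20))
  bd <- aggregate_costs(items, absentee)
  expect_equal(bd$per_category$mean_per_patient[
    bd$per_category$category == "visits"], 1.5)  # (1 + 2) / 2
  expect_equal(bd$indirect_total, 80)             # (120 + 40) / 2
  expect_equal(bd$n_patients, 2)
})

test_that("aggregation rejects empty input and unknown categories", {
  expect_error(aggregate_costs(tibble::tibble(patient_id = character(),
                                              category = character(),
                                              amount = numeric(),
                                              currency = character())),
               class = "radcea_invalid_input")
  expect_error(aggregate_costs(tibble::tibble(patient_id = "a",
                                              category = "helicopter",
                                              amount = 1, currency = "USD")),
               class = "radcea_invalid_input")
})

test_that("whole-dollar reporting truncates rather than rounds", {
  expect_equal(truncate_dollars(13761.33), 13761)
  expect_equal(truncate_dollars(7.00), 7)
  expect_equal(truncate_dollars(9772.91), 9772)
  expect_error(truncate_dollars(-0.5), class = "radcea_invalid_input")
})

test_that("reported totals disagreeing with column sums are flagged", {
  crt_means <- c(visits = 17.57, laboratory = 83.12, diagnosis = 175.17,
                 radiotherapy = 9497.05)
  bd <- aggregate_costs(one_patient_items(crt_means))
  flags <- flag_total_discrepancies(bd, c(direct_medical_total = 9772.92))
  expect_true(flags$flagged)                     # one printed cent off
  expect_equal(flags$recomputed, 9772.91, tolerance = 1e-9)
  ok <- flag_total_discrepancies(bd, c(direct_medical_total = 9772.91))
  expect_false(ok$flagged)
})

test_that("cost and absenteeism CSVs round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_study_config(n_patients = 6, n_reference = 3,
                                cost_cv = 0, seed = 5)
  paths <- write_synthetic_study(cfg, dir)
  items <- read_cost_records(paths[1])
  absentee <- read_absenteeism(paths[2])
  expect_setequal(unique(items$arm), c("3D-CRT", "IMRT"))
  expect_equal(nrow(absentee), 6)
  bd <- aggregate_costs(items[items$arm == "IMRT", ],
                        absentee[absentee$arm == "IMRT", ])
  expect_equal(bd$direct_medical_total, 13363.56, tolerance = 1e-6)
})
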