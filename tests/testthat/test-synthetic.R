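test_that("the same seed reproduces the same hospital", {
  a <- simulate_hospital(small_sim_params(123))
  b <- simulate_hospital(small_sim_params(123))
  expect_identical(a$activity, b$activity)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$truth$breakdowns, b$truth$breakdowns)
  c <- simulate_hospital(small_sim_params(124))
  expect_false(identical(a$activity, c$activity))
})

test_that("exact-mode ledgers give back the ground-truth rates", {
  for (seed in c(1, 9, 31)) {
    h <- simulate_hospital(small_sim_params(seed))
    sch <- compute_unit_costs(h$ledger, h$census,
                              cost_config(period = h$census$period))
    truth <- h$truth$rates
    for (f in c("uicc_daily", "icu_daily", "exam_unit", "nir_admission",
                "uicc_daily_pers", "icu_daily_pers", "exam_unit_pers",
                "nir_admission_pers")) {
      expect_lte(rel_diff(sch[[f]], truth[[f]]), 1e-12)
    }
    expect_lte(max(rel_diff(sch$or_indirect_per_surgery,
                            truth$or_indirect_per_surgery)), 1e-12)
    expect_lte(max(rel_diff(sch$or_per_surgery_pers,
                            truth$or_per_surgery_pers)), 1e-12)
  }
})

test_that("per-room synthetic ledgers are also recovered", {
  params <- small_sim_params(
    4, or_mode = "per_room",
    true_rates = list(
      uicc_daily = 150, icu_daily = 900, exam_unit = 25, nir_admission = 40,
      or_per_surgery = c(R1 = 400, R2 = 700, R3 = 900),
      uicc_daily_pers = 250, icu_daily_pers = 1400, exam_unit_pers = 15,
      nir_admission_pers = 60,
      or_per_surgery_pers = c(R1 = 900, R2 = 1200, R3 = 1500)
    )
  )
  h <- simulate_hospital(params)
  sch <- compute_unit_costs(h$ledger, h$census,
                            cost_config(or_mode = "per_room",
                                        period = h$census$period))
  expect_lte(max(rel_diff(sch$or_indirect_per_surgery,
                          h$truth$rates$or_indirect_per_surgery)), 1e-12)
  expect_lte(max(rel_diff(sch$or_per_surgery_pers,
                          h$truth$rates$or_per_surgery_pers)), 1e-12)
})

test_that("degenerate distributions reduce to the hand-computed case", {
  params <- simulation_params(
    seed = 1,
    n_procedures = 1,
    surgeries_per_procedure = list(fixed = 1),
    n_other_admissions = 0,
    los_uicc_dist = list(fixed = 5),
    los_icu_dist = list(fixed = 1),
    exam_dist = list(fixed = 5),
    direct_cost_dist = list(fixed = 150),
    rooms = c(R1 = 1),
    true_rates = list(
      uicc_daily = 10, icu_daily = 30, exam_unit = 5, nir_admission = 10,
      or_per_surgery = 100,
      uicc_daily_pers = 6, icu_daily_pers = 10, exam_unit_pers = 2.5,
      nir_admission_pers = 5, or_per_surgery_pers = 50
    )
  )
  h <- simulate_hospital(params)
  expect_equal(h$truth$breakdowns$total, 472.5)
  engine <- cost_all_procedures(h$ledger, h$activity, h$census,
                                cost_config(period = h$census$period))
  expect_equal(engine$total, 472.5)
  expect_equal(engine$operating_room_cost, 250)
  expect_equal(engine$hospitalization_cost, 115)
  expect_equal(engine$personnel_cost, 107.5)
})

test_that("perturbed ledgers break recovery but never conservation", {
  h <- simulate_hospital(small_sim_params(8, noise_mode = "perturbed",
                                          noise_sd = 0.2))
  sch <- compute_unit_costs(h$ledger, h$census,
                            cost_config(period = h$census$period))
  cons <- check_conservation(sch, h$ledger)
  expect_lte(max(cons$rel_error), 1e-9)
  expect_gt(rel_diff(sch$uicc_daily, h$truth$rates$uicc_daily), 1e-6)
})

test_that("impossible parameter sets are refused", {
  params <- small_sim_params(3, los_icu_dist = list(fixed = 0),
                             other_icu = list(p = 0, meanlog = 0, sdlog = 0))
  expect_error(simulate_hospital(params), "zero ICU patient-days")
})

test_that("fixtures round-trip and the engine reproduces the truth", {
  dir <- withr::local_tempdir()
  h <- simulate_hospital(small_sim_params(21))
  write_fixture(h, dir)
  expect_setequal(list.files(dir),
                  c("ledger.csv", "encounters.csv", "census.csv", "truth.csv"))
  config <- cost_config(period = h$census$period)
  ledger <- read_ledger(file.path(dir, "ledger.csv"), config)
  activity <- read_encounters(file.path(dir, "encounters.csv"), config)
  census <- read_census(file.path(dir, "census.csv"), config)
  expect_equal(nrow(validation_report(ledger)$errors), 0)
  expect_equal(nrow(validation_report(activity)$errors), 0)
  breakdowns <- cost_all_procedures(ledger, activity, census, config)
  truth <- h$truth$breakdowns
  expect_equal(breakdowns$procedure_code, truth$procedure_code)
  for (col in setdiff(names(truth), "procedure_code")) {
    expect_lte(max(rel_diff(breakdowns[[col]], truth[[col]])), 1e-9)
  }
})

test_that("a surgical-only hospital has equal totals and surgical counts", {
  h <- simulate_hospital(small_sim_params(13, n_other_admissions = 0))
  expect_equal(h$census$surgical_admissions, h$census$total_admissions)
  expect_equal(h$census$surgical_exams, h$census$total_exams)
})
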