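test_that("the three blocks reproduce the hand-computed micro-example", {
  sch <- worked_schedule()
  prof <- profile_procedure(worked_encounters(), "X")

  or <- cost_operating_room(prof, sch)
  expect_equal(or$or_direct, 150)
  expect_equal(or$or_indirect, 100)
  expect_equal(or$operating_room_cost, 250)

  hosp <- cost_hospitalization(prof, sch)
  expect_equal(hosp$hosp_uicc, 50)   # 10/day x 5 days
  expect_equal(hosp$hosp_icu, 30)    # 30/day x 1 day
  expect_equal(hosp$hosp_exams, 25)  # 5/exam x 5 exams
  expect_equal(hosp$hosp_nir, 10)    # per admission
  expect_equal(hosp$hospitalization_cost, 115)

  pers <- cost_personnel(prof, sch)
  expect_equal(pers$pers_or, 50)
  expect_equal(pers$pers_uicc, 30)
  expect_equal(pers$pers_icu, 10)
  expect_equal(pers$pers_exams, 12.5)
  expect_equal(pers$pers_nir, 5)
  expect_equal(pers$personnel_cost, 107.5)

  b <- cost_surgical_hospitalization(prof, sch)
  expect_equal(b$total, 472.5)
  expect_equal(b$total,
               b$operating_room_cost + b$hospitalization_cost + b$personnel_cost)
})

test_that("degenerate schedules reduce the blocks to their direct parts", {
  zero_ledger <- worked_ledger()
  zero_ledger$amount <- 0
  sch0 <- compute_unit_costs(zero_ledger, worked_census())
  prof <- profile_procedure(worked_encounters(), "X")
  expect_equal(cost_operating_room(prof, sch0)$operating_room_cost, 150)
  b <- cost_surgical_hospitalization(prof, sch0)
  expect_equal(b$total, prof$median_direct_cost)

  # a procedure that never enters the ICU pays no ICU per-diem
  enc <- worked_encounters()
  enc$los_icu_days <- 0
  sch <- worked_schedule()
  expect_equal(cost_hospitalization(profile_procedure(enc, "X"), sch)$hosp_icu, 0)

  # zero drivers leave only the per-surgery and per-admission personnel
  enc$los_uicc_days <- 0
  enc$exam_count <- 0L
  pers <- cost_personnel(profile_procedure(enc, "X"), sch)
  expect_equal(pers$personnel_cost, pers$pers_or + pers$pers_nir)
})

test_that("multi-room procedures pay the room-count-weighted rate", {
  ledger <- tibble::tibble(
    period = "2022-01", cost_center = "OPERATING_ROOM",
    room_id = c("R1", "R2"), resource = "Electricity",
    amount = c(500, 900)
  )
  census <- worked_census()  # R1: 5 surgeries, R2: 3
  sch <- compute_unit_costs(ledger, census, cost_config(or_mode = "per_room"))
  expect_equal(sch$or_indirect_per_surgery, c(R1 = 100, R2 = 300))

  enc <- worked_encounters()[1:2, ]
  enc$room_id <- c("R1", "R2")
  prof <- profile_procedure(enc, "X")
  expect_equal(cost_operating_room(prof, sch)$or_indirect, 200)

  prof_bad <- prof
  prof_bad$room_counts <- c(R9 = 2)
  expect_error(cost_operating_room(prof_bad, sch), "R9")
})

test_that("exam cost allocation: per-exam refines the flat surgical share", {
  sch_flat <- worked_schedule(cost_config(exam_mode = "flat_share"))
  prof <- profile_procedure(worked_encounters(), "X")
  flat <- cost_hospitalization(prof, sch_flat)
  # surgical share 40/100 of the 500 total, over 8 surgical admissions
  expect_equal(flat$hosp_exams, 500 * (40 / 100) / 8)
  # flat share ignores the procedure's own exam usage
  heavy <- prof
  heavy$mean_exam_count <- 50
  expect_equal(cost_hospitalization(heavy, sch_flat)$hosp_exams,
               flat$hosp_exams)

  # aggregate equivalence: per-exam allocation summed over all surgical
  # encounters equals the stated surgical proportion of the exam total
  census <- worked_census()
  sch <- worked_schedule()
  expect_equal(sch$exam_unit * census$surgical_exams,
               500 * census$surgical_exams / census$total_exams)
  # same identity for the admission office: per-admission rate summed over
  # surgical admissions is the surgical share of the NIR total
  expect_equal(sch$nir_admission * census$surgical_admissions,
               200 * census$surgical_admissions / census$total_admissions)
})

test_that("indirect costs scale linearly with the ledger", {
  ledger <- worked_ledger()
  census <- worked_census()
  enc <- worked_encounters()
  b1 <- cost_all_procedures(ledger, enc, census)
  scaled <- ledger
  scaled$amount <- scaled$amount * 2.5
  b2 <- cost_all_procedures(scaled, enc, census)
  indirect_cols <- c("or_indirect", "hosp_uicc", "hosp_icu", "hosp_exams",
                     "hosp_nir", "hospitalization_cost", "pers_or",
                     "pers_uicc", "pers_icu", "pers_exams", "pers_nir",
                     "personnel_cost")
  for (col in indirect_cols) {
    expect_equal(b2[[col]], 2.5 * b1[[col]])
  }
  # the direct consumption-note part comes from the encounters, not the
  # ledger, so it is invariant and the total scales in its indirect part
  expect_equal(b2$or_direct, b1$or_direct)
  expect_equal(b2$total - b2$or_direct, 2.5 * (b1$total - b1$or_direct))
})

test_that("a longer ward stay raises only the per-diem components", {
  sch <- worked_schedule()
  prof <- profile_procedure(worked_encounters(), "X")
  longer <- prof
  longer$mean_los_uicc <- prof$mean_los_uicc + 2
  b0 <- cost_surgical_hospitalization(prof, sch)
  b1 <- cost_surgical_hospitalization(longer, sch)
  expect_gt(b1$hosp_uicc, b0$hosp_uicc)
  expect_gt(b1$pers_uicc, b0$pers_uicc)
  for (col in c("or_direct", "or_indirect", "hosp_icu", "hosp_exams",
                "hosp_nir", "pers_or", "pers_icu", "pers_exams", "pers_nir")) {
    expect_equal(b1[[col]], b0[[col]])
  }
})

test_that("the median shields the direct cost from an expensive outlier", {
  enc <- worked_encounters()
  spiked <- enc
  spiked$direct_supplies_cost[which.max(enc$direct_supplies_cost)] <- 3 * 200
  sch <- worked_schedule()
  expect_equal(
    cost_operating_room(profile_procedure(spiked, "X"), sch)$or_direct,
    cost_operating_room(profile_procedure(enc, "X"), sch)$or_direct
  )
})

test_that("a homogeneous hospital splits the whole ledger evenly", {
  # all encounters identical and the hospital's only activity: each
  # hospitalization absorbs grand ledger total / n on top of its own
  # consumption note
  n <- 6
  one <- worked_encounters()[2, ]
  enc <- dplyr::bind_rows(lapply(1:n, function(i) {
    row <- one
    row$encounter_id <- paste0("e", i)
    row
  }))
  census <- build_census(enc)
  ledger <- worked_ledger()
  b <- cost_all_procedures(ledger, enc, census)
  expect_equal(b$total, sum(ledger$amount) / n + one$direct_supplies_cost)
})

test_that("costing all procedures equals costing each alone", {
  encY <- worked_encounters()
  encY$encounter_id <- c("f1", "f2", "f3")
  encY$procedure_code <- "Y"
  encY$room_id <- "R2"
  encY$direct_supplies_cost <- c(300, 80, 90)
  enc <- dplyr::bind_rows(worked_encounters(), encY)
  census <- worked_census()
  all_b <- cost_all_procedures(worked_ledger(), enc, census)
  expect_equal(all_b$procedure_code, c("X", "Y"))
  sch <- worked_schedule()
  for (code in c("X", "Y")) {
    solo <- cost_surgical_hospitalization(profile_procedure(enc, code), sch)
    expect_equal(all_b[all_b$procedure_code == code, ], solo,
                 ignore_attr = TRUE)
  }
})

test_that("engine output equals the per-patient bottom-up accumulation", {
  for (seed in c(5, 29)) {
    h <- simulate_hospital(small_sim_params(seed))
    config <- cost_config(period = h$census$period)
    sch <- compute_unit_costs(h$ledger, h$census, config)
    engine <- cost_all_procedures(h$ledger, h$activity, h$census, config)
    oracle <- oracle_totals(h$encounters, sch)
    expect_equal(engine$procedure_code, oracle$procedure_code)
    expect_lte(max(rel_diff(engine$total, oracle$total)), 1e-9)
    expect_lte(max(rel_diff(engine$operating_room_cost,
                            oracle$operating_room_cost)), 1e-9)
    expect_lte(max(rel_diff(engine$hospitalization_cost,
                            oracle$hospitalization_cost)), 1e-9)
    expect_lte(max(rel_diff(engine$personnel_cost,
                            oracle$personnel_cost)), 1e-9)
  }
})

test_that("an encounter table with no surgeries yields an empty report", {
  other_only <- tibble::tibble(
    encounter_id = "o1", period = "2022-01", type = "other",
    procedure_code = NA_character_, room_id = NA_character_,
    direct_supplies_cost = NA_real_,
    los_uicc_days = 0, los_icu_days = 0, exam_count = 2L
  )
  ledger <- worked_ledger()
  ledger$amount[ledger$cost_center %in% c("OPERATING_ROOM", "UICC", "ICU")] <- 0
  expect_warning(
    b <- cost_all_procedures(ledger, other_only),
    "no surgical encounters"
  )
  expect_equal(nrow(b), 0)
  expect_equal(ncol(b), 16)
})
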