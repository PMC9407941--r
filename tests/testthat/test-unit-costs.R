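test_that("unit rates divide center totals by their drivers", {
  sch <- worked_schedule()
  expect_equal(sch$uicc_daily, 10)
  expect_equal(sch$icu_daily, 30)
  expect_equal(sch$exam_unit, 5)
  expect_equal(sch$nir_admission, 10)
  expect_equal(sch$or_indirect_per_surgery, c(R1 = 100, R2 = 100))
  expect_equal(sch$uicc_daily_pers, 6)
  expect_equal(sch$icu_daily_pers, 10)
  expect_equal(sch$exam_unit_pers, 2.5)
  expect_equal(sch$nir_admission_pers, 5)
  expect_equal(sch$or_per_surgery_pers, c(R1 = 50, R2 = 50))
})

test_that("a zero ledger yields all-zero rates", {
  ledger <- worked_ledger()
  ledger$amount <- 0
  sch <- compute_unit_costs(ledger, worked_census())
  tab <- rate_table(sch)
  expect_true(all(tab$non_personnel == 0))
  expect_true(all(tab$personnel == 0))
})

test_that("per-room sub-centers divide each room total by its surgeries", {
  ledger <- tibble::tibble(
    period = "2022-01",
    cost_center = "OPERATING_ROOM",
    room_id = c("R1", "R2"),
    resource = "Electricity",
    amount = c(500, 300)
  )
  config <- cost_config(or_mode = "per_room")
  sch <- compute_unit_costs(ledger, worked_census(), config)
  expect_equal(sch$or_indirect_per_surgery, c(R1 = 100, R2 = 100))

  # unequal rooms separate under per-room but not under pooled
  ledger$amount <- c(1000, 300)
  sch2 <- compute_unit_costs(ledger, worked_census(), config)
  expect_equal(sch2$or_indirect_per_surgery, c(R1 = 200, R2 = 100))
  pooled <- compute_unit_costs(
    dplyr::mutate(ledger, room_id = NA_character_) |>
      dplyr::mutate(resource = c("Electricity", "Clothing")),
    worked_census(), cost_config(or_mode = "pooled")
  )
  expect_equal(unname(pooled$or_indirect_per_surgery), c(162.5, 162.5))
})

test_that("rate times denominator reconstructs every ledger total", {
  for (seed in c(3, 17, 23)) {
    h <- simulate_hospital(small_sim_params(seed))
    sch <- compute_unit_costs(h$ledger, h$census,
                              cost_config(period = h$census$period))
    cons <- check_conservation(sch, h$ledger)
    expect_lte(max(cons$rel_error), 1e-9)
  }
})

test_that("stranded cost (positive total, zero driver) is a hard error", {
  ledger <- worked_ledger()
  census <- hospital_census("2022-01", 20, 8, 100, 40, 100, 0, c(R1 = 5, R2 = 3))
  expect_error(compute_unit_costs(ledger, census), "ICU.*zero activity")

  # zero cost with a zero driver is fine: the rate is 0
  ledger$amount[ledger$cost_center == "ICU"] <- 0
  sch <- compute_unit_costs(ledger, census)
  expect_equal(sch$icu_daily, 0)
  expect_equal(sch$icu_daily_pers, 0)
})

test_that("malformed ledgers are rejected", {
  bad <- worked_ledger()
  bad$amount[3] <- -1
  expect_error(compute_unit_costs(bad, worked_census()), "non-negative")

  stray_room <- worked_ledger()
  stray_room$room_id[stray_room$cost_center == "UICC"] <- "R1"
  expect_error(compute_unit_costs(stray_room, worked_census()),
               "only meaningful for OPERATING_ROOM")

  dup <- dplyr::bind_rows(worked_ledger(), worked_ledger()[1, ])
  expect_error(compute_unit_costs(dup, worked_census()), "duplicate")

  wrong_period <- worked_ledger()
  wrong_period$period[1] <- "2022-02"
  expect_error(compute_unit_costs(wrong_period, worked_census()),
               "same single period")
})

test_that("extended personnel categories move resources between splits", {
  ledger <- worked_ledger()
  ledger$resource[ledger$cost_center == "UICC" &
                    ledger$resource == "Electricity"] <- "Reception"
  config <- cost_config(personnel_categories = c("Personnel", "Reception"))
  sch <- compute_unit_costs(ledger, worked_census(), config)
  expect_equal(sch$uicc_daily, 0)
  expect_equal(sch$uicc_daily_pers, 16) # (1000 + 600) / 100
})
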