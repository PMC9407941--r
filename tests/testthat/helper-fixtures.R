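# Hand-checkable micro-hospital: one period, two operating rooms, every
# ledger total divisible by its denominator so all unit rates are exact.
worked_ledger <- function() {
  tibble::tibble(
    period = "2022-01",
    cost_center = rep(c("OPERATING_ROOM", "UICC", "ICU", "EXAMS", "NIR"), each = 2),
    room_id = NA_character_,
    resource = rep(c("Electricity", "Personnel"), 5),
    amount = c(800, 400, 1000, 600, 900, 300, 500, 250, 200, 100)
  )
}

worked_census <- function() {
  hospital_census(
    period = "2022-01",
    total_admissions = 20, surgical_admissions = 8,
    total_exams = 100, surgical_exams = 40,
    uicc_patient_days = 100, icu_patient_days = 30,
    surgeries_by_room = c(R1 = 5, R2 = 3)
  )
}

worked_encounters <- function() {
  tibble::tibble(
    encounter_id = c("e1", "e2", "e3"),
    period = "2022-01",
    type = "surgical",
    procedure_code = "X",
    room_id = "R1",
    direct_supplies_cost = c(120, 150, 200),
    los_uicc_days = c(4, 6, 5),
    los_icu_days = c(0, 2, 1),
    exam_count = c(4L, 6L, 5L)
  )
}

worked_schedule <- function(config = cost_config()) {
  compute_unit_costs(worked_ledger(), worked_census(), config)
}

# Independent bottom-up oracle, written with explicit per-encounter loops
# so it shares no code path with the package: price each encounter at the
# unit rates, then take median(direct) + mean(indirect) per procedure.
oracle_totals <- function(surgical, schedule) {
  codes <- sort(unique(surgical$procedure_code))
  out <- data.frame(procedure_code = codes, total = NA_real_,
                    operating_room_cost = NA_real_,
                    hospitalization_cost = NA_real_,
                    personnel_cost = NA_real_)
  for (k in seq_along(codes)) {
    e <- surgical[surgical$procedure_code == codes[k], , drop = FALSE]
    n <- nrow(e)
    ind_np <- numeric(n)
    ind_or <- numeric(n)
    ind_pers <- numeric(n)
    for (i in seq_len(n)) {
      r <- e$room_id[i]
      ind_or[i] <- schedule$or_indirect_per_surgery[[r]]
      ind_np[i] <- schedule$uicc_daily * e$los_uicc_days[i] +
        schedule$icu_daily * e$los_icu_days[i] +
        schedule$exam_unit * e$exam_count[i] +
        schedule$nir_admission
      ind_pers[i] <- schedule$or_per_surgery_pers[[r]] +
        schedule$uicc_daily_pers * e$los_uicc_days[i] +
        schedule$icu_daily_pers * e$los_icu_days[i] +
        schedule$exam_unit_pers * e$exam_count[i] +
        schedule$nir_admission_pers
    }
    direct <- sort(e$direct_supplies_cost)
    med <- if (n %% 2 == 1) {
      direct[(n + 1) / 2]
    } else {
      (direct[n / 2] + direct[n / 2 + 1]) / 2
    }
    out$operating_room_cost[k] <- med + mean(ind_or)
    out$hospitalization_cost[k] <- mean(ind_np)
    out$personnel_cost[k] <- mean(ind_pers)
    out$total[k] <- med + mean(ind_or) + mean(ind_np) + mean(ind_pers)
  }
  out
}

rel_diff <- function(a, b) {
  ifelse(b == 0, abs(a), abs(a - b) / abs(b))
}

small_sim_params <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_procedures = 6L,
         surgeries_per_procedure = list(min = 2, lambda = 5),
         n_other_admissions = 40L),
    list(...)
  )
  do.call(simulation_params, args)
}
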