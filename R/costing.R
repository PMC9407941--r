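#' Operating-room cost block
#'
#' Sum of the direct unit cost (median consumption-note value of supplies
#' and medicines spent during surgery) and the indirect cost (everything
#' the ledger assigns to the surgical center except personnel, prorated by
#' the number of surgeries in each operating room). A procedure performed
#' in several rooms is charged the room-count-weighted mean of the
#' per-room rates.
#'
#' @param profile A [profile_procedure()] result.
#' @param schedule A [compute_unit_costs()] result.
#' @return Named list: `or_direct`, `or_indirect`, `operating_room_cost`.
#' @export
cost_operating_room <- function(profile, schedule) {
  stopifnot(inherits(profile, "procedure_profile"),
            inherits(schedule, "unit_cost_schedule"))
  or_indirect <- room_weighted_rate(profile, schedule$or_indirect_per_surgery)
  list(
    or_direct = profile$median_direct_cost,
    or_indirect = or_indirect,
    operating_room_cost = profile$median_direct_cost + or_indirect
  )
}

room_weighted_rate <- function(profile, per_room_rate) {
  rooms <- names(profile$room_counts)
  missing_rooms <- setdiff(rooms, names(per_room_rate))
  if (length(missing_rooms) > 0) {
    rlang::abort(paste0(
      "no per-surgery rate for room(s): ", paste(missing_rooms, collapse = ", ")
    ))
  }
  sum((profile$room_counts / profile$n) * per_room_rate[rooms])
}

#' Hospitalization cost block
#'
#' Pre- and postoperative episode cost, personnel excluded: the UICC and
#' ICU daily rates times the procedure's mean length of stay in each unit,
#' the exam cost, and the admission-office (NIR) cost. With
#' `exam_mode = "per_exam"` the exam cost is the per-exam rate times the
#' procedure's mean exam count; with `"flat_share"` it is the surgical
#' share of the exam-center total divided evenly over surgical admissions
#' (the same value for every procedure). The NIR per-admission rate is
#' charged once per hospitalization.
#'
#' @inheritParams cost_operating_room
#' @return Named list: `hosp_uicc`, `hosp_icu`, `hosp_exams`, `hosp_nir`,
#'   `hospitalization_cost`.
#' @export
cost_hospitalization <- function(profile, schedule) {
  stopifnot(inherits(profile, "procedure_profile"),
            inherits(schedule, "unit_cost_schedule"))
  hosp_uicc <- schedule$uicc_daily * profile$mean_los_uicc
  hosp_icu <- schedule$icu_daily * profile$mean_los_icu
  hosp_exams <- exam_component(profile, schedule, schedule$exam_unit)
  hosp_nir <- schedule$nir_admission
  list(
    hosp_uicc = hosp_uicc,
    hosp_icu = hosp_icu,
    hosp_exams = hosp_exams,
    hosp_nir = hosp_nir,
    hospitalization_cost = hosp_uicc + hosp_icu + hosp_exams + hosp_nir
  )
}

exam_component <- function(profile, schedule, unit_rate) {
  if (schedule$config$exam_mode == "per_exam") {
    unit_rate * profile$mean_exam_count
  } else {
    census <- schedule$census
    if (census$surgical_admissions <= 0) {
      rlang::abort("flat_share exam allocation needs surgical admissions in the census")
    }
    unit_rate * census$surgical_exams / census$surgical_admissions
  }
}

#' Personnel cost block
#'
#' Personnel cost is apportioned with the same drivers as the other two
#' blocks but kept segregated, so hospitals with different hiring models
#' remain comparable: the operating-room personnel total split by the
#' proportion of surgeries in each room, plus per-day personnel rates for
#' UICC and ICU times the mean stay, per-exam personnel cost, and the NIR
#' per-admission personnel cost.
#'
#' @inheritParams cost_operating_room
#' @return Named list: `pers_or`, `pers_uicc`, `pers_icu`, `pers_exams`,
#'   `pers_nir`, `personnel_cost`.
#' @export
cost_personnel <- function(profile, schedule) {
  stopifnot(inherits(profile, "procedure_profile"),
            inherits(schedule, "unit_cost_schedule"))
  pers_or <- room_weighted_rate(profile, schedule$or_per_surgery_pers)
  pers_uicc <- schedule$uicc_daily_pers * profile$mean_los_uicc
  pers_icu <- schedule$icu_daily_pers * profile$mean_los_icu
  pers_exams <- exam_component(profile, schedule, schedule$exam_unit_pers)
  pers_nir <- schedule$nir_admission_pers
  list(
    pers_or = pers_or,
    pers_uicc = pers_uicc,
    pers_icu = pers_icu,
    pers_exams = pers_exams,
    pers_nir = pers_nir,
    personnel_cost = pers_or + pers_uicc + pers_icu + pers_exams + pers_nir
  )
}

#' Cost of one surgical hospitalization
#'
#' Assembles the three blocks — Operating room, Hospitalization, Personnel
#' — into the full admission-to-discharge cost of a procedure.
#'
#' @inheritParams cost_operating_room
#' @return A one-row tibble of class `cost_breakdown` with the block
#'   sub-components, block sums and the grand `total`.
#' @export
cost_surgical_hospitalization <- function(profile, schedule) {
  or <- cost_operating_room(profile, schedule)
  hosp <- cost_hospitalization(profile, schedule)
  pers <- cost_personnel(profile, schedule)
  out <- tibble::tibble(
    procedure_code = profile$procedure_code,
    or_direct = or$or_direct,
    or_indirect = or$or_indirect,
    operating_room_cost = or$operating_room_cost,
    hosp_uicc = hosp$hosp_uicc,
    hosp_icu = hosp$hosp_icu,
    hosp_exams = hosp$hosp_exams,
    hosp_nir = hosp$hosp_nir,
    hospitalization_cost = hosp$hospitalization_cost,
    pers_or = pers$pers_or,
    pers_uicc = pers$pers_uicc,
    pers_icu = pers$pers_icu,
    pers_exams = pers$pers_exams,
    pers_nir = pers$pers_nir,
    personnel_cost = pers$personnel_cost,
    total = or$operating_room_cost + hosp$hospitalization_cost + pers$personnel_cost
  )
  class(out) <- c("cost_breakdown", class(out))
  out
}

#' Cost every procedure of a period
#'
#' Runs the full pipeline: derive the unit-cost schedule from the ledger
#' and census, profile each distinct procedure code, and compute its
#' three-block breakdown. One accounting period per call.
#'
#' @param ledger Ledger data frame (see [compute_unit_costs()]).
#' @param encounters Data frame of encounters; may include non-surgical
#'   rows (`type == "other"`), which feed only the census.
#' @param census Optional [hospital_census()]; derived from `encounters`
#'   via [build_census()] when omitted (then `encounters` must cover all
#'   hospitalizations, not only surgical ones).
#' @param config A [cost_config()].
#' @return A tibble of class `cost_breakdown`, one row per procedure code,
#'   sorted by code; empty (with a warning) when there are no surgical
#'   encounters.
#' @export
cost_all_procedures <- function(ledger, encounters, census = NULL,
                                config = cost_config()) {
  encounters <- tibble::as_tibble(encounters)
  if (is.null(census)) {
    census <- build_census(encounters, period = config$period)
  }
  surgical <- if ("type" %in% names(encounters)) {
    encounters[encounters$type == "surgical", , drop = FALSE]
  } else {
    encounters
  }
  if (nrow(surgical) > 0 && "period" %in% names(surgical)) {
    if (!all(as.character(surgical$period) == census$period)) {
      rlang::abort("encounters and census must cover the same single period")
    }
  }
  schedule <- compute_unit_costs(ledger, census, config)
  codes <- sort(unique(surgical$procedure_code))
  if (length(codes) == 0) {
    rlang::warn("no surgical encounters: returning an empty cost table")
    empty <- cost_breakdown_prototype()
    return(empty)
  }
  rows <- lapply(codes, function(code) {
    cost_surgical_hospitalization(profile_procedure(surgical, code), schedule)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cost_breakdown", setdiff(class(out), "cost_breakdown"))
  out
}

cost_breakdown_prototype <- function() {
  out <- tibble::tibble(
    procedure_code = character(),
    or_direct = numeric(), or_indirect = numeric(),
    operating_room_cost = numeric(),
    hosp_uicc = numeric(), hosp_icu = numeric(), hosp_exams = numeric(),
    hosp_nir = numeric(), hospitalization_cost = numeric(),
    pers_or = numeric(), pers_uicc = numeric(), pers_icu = numeric(),
    pers_exams = numeric(), pers_nir = numeric(), personnel_cost = numeric(),
    total = numeric()
  )
  class(out) <- c("cost_breakdown", class(out))
  out
}
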