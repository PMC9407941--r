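#' Derive the unit-cost schedule from a ledger and a census
#'
#' Apportions each cost center's ledger total by its cost driver to obtain
#' unit rates, separately for non-personnel and personnel resources:
#'
#' * UICC and ICU: center total / patient-days in the unit (daily rate);
#' * Exams: center total / hospital-wide exam count (per-exam rate);
#' * NIR (admission office): center total / total admissions (per-admission
#'   rate — equivalent to prorating the center total by the surgical share
#'   of admissions and then dividing over the surgical admissions);
#' * Operating room: in `pooled` mode the surgical-center total is split by
#'   the proportion of surgeries performed in each operating room, which
#'   yields one uniform per-surgery rate; in `per_room` mode each room's
#'   ledger sub-center total is divided by that room's surgery count.
#'
#' Supplies and medicines consumed during surgery never appear in the
#' operating-room ledger: they are direct costs carried by each surgery's
#' consumption note.
#'
#' A center with positive cost but a zero driver total is an error (the
#' cost could not be absorbed by any activity); zero cost with a zero
#' driver yields a zero rate.
#'
#' @param ledger Data frame with columns `period`, `cost_center`,
#'   `room_id` (may be `NA` except for per-room operating-room entries),
#'   `resource` and non-negative `amount`; one row per
#'   (period, center, room, resource).
#' @param census A [hospital_census()] for the same period.
#' @param config A [cost_config()].
#'
#' @return An object of class `unit_cost_schedule` with fields
#'   `uicc_daily`, `icu_daily`, `exam_unit`, `nir_admission`,
#'   `or_indirect_per_surgery` (named by room), their `_pers` personnel
#'   counterparts, and the `census` and `config` used.
#' @export
compute_unit_costs <- function(ledger, census, config = cost_config()) {
  stopifnot(inherits(census, "hospital_census"))
  ledger <- as_ledger_tbl(ledger)
  if (nrow(ledger) > 0) {
    periods <- unique(ledger$period)
    if (length(periods) > 1 || !identical(as.character(periods), census$period)) {
      rlang::abort("ledger and census must cover the same single period")
    }
  }
  if (any(is.na(ledger$amount) | ledger$amount < 0)) {
    rlang::abort("ledger amounts must be non-negative")
  }
  bad_center <- setdiff(unique(ledger$cost_center), cost_centers())
  if (length(bad_center) > 0) {
    rlang::abort(paste0("unknown cost center(s): ", paste(bad_center, collapse = ", ")))
  }
  off_or <- ledger$cost_center != "OPERATING_ROOM" & !is.na(ledger$room_id)
  if (any(off_or)) {
    rlang::abort("room_id is only meaningful for OPERATING_ROOM ledger entries")
  }

  is_pers <- ledger$resource %in% config$personnel_categories
  center_total <- function(center, pers) {
    sum(ledger$amount[ledger$cost_center == center & is_pers == pers])
  }
  rate_of <- function(total, denom, what) {
    if (total == 0) return(0)
    if (denom <= 0) {
      rlang::abort(paste0(
        "cost center ", what, " has positive ledger total (", format(total),
        ") but a zero activity denominator: unit rate undefined"
      ))
    }
    total / denom
  }

  rooms <- names(census$surgeries_by_room)
  total_surgeries <- sum(census$surgeries_by_room)
  or_rates <- function(pers) {
    in_or <- ledger$cost_center == "OPERATING_ROOM" & is_pers == pers
    if (config$or_mode == "pooled") {
      total <- sum(ledger$amount[in_or])
      rate <- rate_of(total, total_surgeries, "OPERATING_ROOM")
      stats::setNames(rep(rate, length(rooms)), rooms)
    } else {
      or_rows <- ledger[in_or, , drop = FALSE]
      if (nrow(or_rows) > 0 && any(is.na(or_rows$room_id) | or_rows$room_id == "")) {
        rlang::abort("or_mode = 'per_room' requires a room_id on every OPERATING_ROOM ledger entry")
      }
      stray <- setdiff(unique(or_rows$room_id), rooms)
      if (length(stray) > 0) {
        rlang::abort(paste0(
          "OPERATING_ROOM ledger rooms absent from the census: ",
          paste(stray, collapse = ", ")
        ))
      }
      vapply(rooms, function(r) {
        total <- sum(or_rows$amount[or_rows$room_id == r])
        rate_of(total, census$surgeries_by_room[[r]],
                paste0("OPERATING_ROOM room ", r))
      }, numeric(1))
    }
  }

  structure(
    list(
      period = census$period,
      uicc_daily = rate_of(center_total("UICC", FALSE), census$uicc_patient_days, "UICC"),
      icu_daily = rate_of(center_total("ICU", FALSE), census$icu_patient_days, "ICU"),
      exam_unit = rate_of(center_total("EXAMS", FALSE), census$total_exams, "EXAMS"),
      nir_admission = rate_of(center_total("NIR", FALSE), census$total_admissions, "NIR"),
      or_indirect_per_surgery = or_rates(FALSE),
      uicc_daily_pers = rate_of(center_total("UICC", TRUE), census$uicc_patient_days, "UICC"),
      icu_daily_pers = rate_of(center_total("ICU", TRUE), census$icu_patient_days, "ICU"),
      exam_unit_pers = rate_of(center_total("EXAMS", TRUE), census$total_exams, "EXAMS"),
      nir_admission_pers = rate_of(center_total("NIR", TRUE), census$total_admissions, "NIR"),
      or_per_surgery_pers = or_rates(TRUE),
      census = census,
      config = config
    ),
    class = "unit_cost_schedule"
  )
}

# Coerce a ledger-shaped data frame, filling an absent room_id column.
as_ledger_tbl <- function(ledger) {
  ledger <- tibble::as_tibble(ledger)
  needed <- c("period", "cost_center", "resource", "amount")
  missing_cols <- setdiff(needed, names(ledger))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "ledger lacks required columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"room_id" %in% names(ledger)) {
    ledger$room_id <- NA_character_
  }
  ledger$room_id[!is.na(ledger$room_id) & ledger$room_id == ""] <- NA_character_
  key <- paste(ledger$period, ledger$cost_center, ledger$room_id, ledger$resource)
  if (anyDuplicated(key)) {
    rlang::abort("duplicate (period, cost_center, room_id, resource) ledger entries")
  }
  ledger
}

#' Tabulate a unit-cost schedule
#'
#' @param schedule A `unit_cost_schedule`.
#' @return A tibble with one row per rate component (operating-room rows
#'   repeated per room), columns `component`, `room_id`, `non_personnel`,
#'   `personnel`.
#' @export
rate_table <- function(schedule) {
  stopifnot(inherits(schedule, "unit_cost_schedule"))
  rooms <- names(schedule$or_indirect_per_surgery)
  dplyr::bind_rows(
    tibble::tibble(
      component = c("uicc_daily", "icu_daily", "exam_unit", "nir_admission"),
      room_id = NA_character_,
      non_personnel = c(schedule$uicc_daily, schedule$icu_daily,
                        schedule$exam_unit, schedule$nir_admission),
      personnel = c(schedule$uicc_daily_pers, schedule$icu_daily_pers,
                    schedule$exam_unit_pers, schedule$nir_admission_pers)
    ),
    tibble::tibble(
      component = rep("or_per_surgery", length(rooms)),
      room_id = rooms,
      non_personnel = unname(schedule$or_indirect_per_surgery),
      personnel = unname(schedule$or_per_surgery_pers)
    )
  )
}

#' Check rate-times-denominator conservation against a ledger
#'
#' Every unit rate multiplied by its activity denominator must reconstruct
#' the cost-center ledger total it was derived from; this is the defining
#' property of top-down apportionment (no cost is created or lost).
#'
#' @param schedule A `unit_cost_schedule`.
#' @param ledger The ledger it was computed from.
#' @return Tibble with `component`, `ledger_total`, `reconstructed` and
#'   `rel_error` (absolute error where the total is zero).
#' @export
check_conservation <- function(schedule, ledger) {
  stopifnot(inherits(schedule, "unit_cost_schedule"))
  ledger <- as_ledger_tbl(ledger)
  census <- schedule$census
  is_pers <- ledger$resource %in% schedule$config$personnel_categories
  total_of <- function(center, pers) {
    sum(ledger$amount[ledger$cost_center == center & is_pers == pers])
  }
  comp <- tibble::tibble(
    component = c("uicc", "icu", "exams", "nir", "operating_room",
                  "uicc_pers", "icu_pers", "exams_pers", "nir_pers",
                  "operating_room_pers"),
    ledger_total = c(
      total_of("UICC", FALSE), total_of("ICU", FALSE), total_of("EXAMS", FALSE),
      total_of("NIR", FALSE), total_of("OPERATING_ROOM", FALSE),
      total_of("UICC", TRUE), total_of("ICU", TRUE), total_of("EXAMS", TRUE),
      total_of("NIR", TRUE), total_of("OPERATING_ROOM", TRUE)
    ),
    reconstructed = c(
      schedule$uicc_daily * census$uicc_patient_days,
      schedule$icu_daily * census$icu_patient_days,
      schedule$exam_unit * census$total_exams,
      schedule$nir_admission * census$total_admissions,
      sum(schedule$or_indirect_per_surgery * census$surgeries_by_room),
      schedule$uicc_daily_pers * census$uicc_patient_days,
      schedule$icu_daily_pers * census$icu_patient_days,
      schedule$exam_unit_pers * census$total_exams,
      schedule$nir_admission_pers * census$total_admissions,
      sum(schedule$or_per_surgery_pers * census$surgeries_by_room)
    )
  )
  comp$rel_error <- ifelse(
    comp$ledger_total == 0,
    abs(comp$reconstructed),
    abs(comp$reconstructed - comp$ledger_total) / comp$ledger_total
  )
  comp
}

#' @export
print.unit_cost_schedule <- function(x, ...) {
  cat("<unit_cost_schedule> period", x$period, "\n")
  cat("  rates (non-personnel / personnel):\n")
  cat(sprintf("    UICC daily:      %g / %g\n", x$uicc_daily, x$uicc_daily_pers))
  cat(sprintf("    ICU daily:       %g / %g\n", x$icu_daily, x$icu_daily_pers))
  cat(sprintf("    per exam:        %g / %g\n", x$exam_unit, x$exam_unit_pers))
  cat(sprintf("    per admission:   %g / %g\n", x$nir_admission, x$nir_admission_pers))
  for (r in names(x$or_indirect_per_surgery)) {
    cat(sprintf("    per surgery %s:  %g / %g\n", r,
                x$or_indirect_per_surgery[[r]], x$or_per_surgery_pers[[r]]))
  }
  invisible(x)
}
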