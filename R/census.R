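#' Construct a hospital activity census
#'
#' A census holds the hospital-wide denominators that turn cost-center
#' ledger totals into unit rates: admissions, exams, patient-days at the
#' surgical ward (UICC) and ICU, and the number of surgeries performed in
#' each operating room over one accounting period.
#'
#' @param period Period identifier shared by all inputs of a run.
#' @param total_admissions Count of all hospitalizations (surgical and
#'   other) in the period; must be positive.
#' @param surgical_admissions Count of surgical hospitalizations,
#'   `<= total_admissions`.
#' @param total_exams Hospital-wide exam count (laboratory + imaging).
#' @param surgical_exams Exams requested for surgical hospitalizations,
#'   `<= total_exams`.
#' @param uicc_patient_days,icu_patient_days Total patient-days in each
#'   unit over the period (fractional allowed).
#' @param surgeries_by_room Named numeric vector, `room_id -> number of
#'   surgeries`; stored sorted by room id.
#'
#' @return An object of class `hospital_census`.
#' @export
hospital_census <- function(period,
                            total_admissions,
                            surgical_admissions,
                            total_exams,
                            surgical_exams,
                            uicc_patient_days,
                            icu_patient_days,
                            surgeries_by_room) {
  if (length(period) != 1 || is.na(period)) {
    rlang::abort("period must be a single non-missing identifier")
  }
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      rlang::abort(paste0(name, " must be a single non-negative number"))
    }
    as.numeric(x)
  }
  total_admissions <- num1(total_admissions, "total_admissions")
  surgical_admissions <- num1(surgical_admissions, "surgical_admissions")
  total_exams <- num1(total_exams, "total_exams")
  surgical_exams <- num1(surgical_exams, "surgical_exams")
  uicc_patient_days <- num1(uicc_patient_days, "uicc_patient_days")
  icu_patient_days <- num1(icu_patient_days, "icu_patient_days")
  if (total_admissions <= 0) {
    rlang::abort("total_admissions must be positive")
  }
  if (surgical_admissions > total_admissions) {
    rlang::abort("surgical_admissions cannot exceed total_admissions")
  }
  if (surgical_exams > total_exams) {
    rlang::abort("surgical_exams cannot exceed total_exams")
  }
  if (length(surgeries_by_room) > 0) {
    if (is.null(names(surgeries_by_room)) || any(names(surgeries_by_room) == "")) {
      rlang::abort("surgeries_by_room must be a named vector (room_id -> count)")
    }
    if (anyDuplicated(names(surgeries_by_room))) {
      rlang::abort("surgeries_by_room has duplicated room ids")
    }
    if (any(is.na(surgeries_by_room)) || any(surgeries_by_room < 0)) {
      rlang::abort("surgeries_by_room counts must be non-negative")
    }
    surgeries_by_room <- surgeries_by_room[order(names(surgeries_by_room))]
  } else {
    surgeries_by_room <- stats::setNames(numeric(0), character(0))
  }
  if (surgical_admissions > 0 && sum(surgeries_by_room) <= 0) {
    rlang::abort("surgical admissions present but no surgeries recorded by room")
  }
  structure(
    list(
      period = as.character(period),
      total_admissions = total_admissions,
      surgical_admissions = surgical_admissions,
      total_exams = total_exams,
      surgical_exams = surgical_exams,
      uicc_patient_days = uicc_patient_days,
      icu_patient_days = icu_patient_days,
      surgeries_by_room = surgeries_by_room
    ),
    class = "hospital_census"
  )
}

#' Aggregate per-hospitalization activity into a census
#'
#' Sums encounter-level drivers — exam counts, UICC and ICU days, surgeries
#' per operating room — over every hospitalization of one period, surgical
#' and non-surgical alike, producing the denominators the unit-rate
#' derivation needs.
#'
#' @param activity A data frame with one row per hospitalization and
#'   columns `type` (`"surgical"` or `"other"`), `exam_count`,
#'   `los_uicc_days`, `los_icu_days`, and for surgical rows `room_id`;
#'   a `period` column is required unless `period` is supplied.
#' @param period Optional period identifier; if the table has a `period`
#'   column it must contain exactly this one value.
#'
#' @return A [hospital_census()].
#' @export
#' @examples
#' activity <- tibble::tibble(
#'   period = "2022-01",
#'   type = c("surgical", "other"),
#'   room_id = c("R1", NA),
#'   exam_count = c(5L, 2L),
#'   los_uicc_days = c(4, 0),
#'   los_icu_days = c(1, 0)
#' )
#' build_census(activity)
build_census <- function(activity, period = NULL) {
  activity <- tibble::as_tibble(activity)
  if (nrow(activity) == 0) {
    rlang::abort("activity table is empty: census denominators are undefined")
  }
  needed <- c("type", "exam_count", "los_uicc_days", "los_icu_days")
  missing_cols <- setdiff(needed, names(activity))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "activity table lacks required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if ("period" %in% names(activity)) {
    periods <- unique(activity$period)
    if (length(periods) > 1) {
      rlang::abort(paste0(
        "activity mixes accounting periods (", paste(periods, collapse = ", "),
        "); run each period separately"
      ))
    }
    if (!is.null(period) && !identical(as.character(periods), as.character(period))) {
      rlang::abort("activity period does not match the requested period")
    }
    period <- periods
  }
  if (is.null(period)) {
    rlang::abort("no period column in activity and no period supplied")
  }
  if (!all(activity$type %in% c("surgical", "other"))) {
    rlang::abort("activity type must be 'surgical' or 'other'")
  }
  surgical <- activity[activity$type == "surgical", , drop = FALSE]
  if (nrow(surgical) > 0) {
    if (!"room_id" %in% names(activity) ||
        any(is.na(surgical$room_id) | surgical$room_id == "")) {
      rlang::abort("every surgical row needs a room_id to tally surgeries by room")
    }
    rooms <- table(surgical$room_id)
    surgeries_by_room <- stats::setNames(as.numeric(rooms), names(rooms))
  } else {
    surgeries_by_room <- stats::setNames(numeric(0), character(0))
  }
  hospital_census(
    period = period,
    total_admissions = nrow(activity),
    surgical_admissions = nrow(surgical),
    total_exams = sum(activity$exam_count),
    surgical_exams = sum(surgical$exam_count),
    uicc_patient_days = sum(activity$los_uicc_days),
    icu_patient_days = sum(activity$los_icu_days),
    surgeries_by_room = surgeries_by_room
  )
}

#' @export
print.hospital_census <- function(x, ...) {
  cat("<hospital_census> period", x$period, "\n")
  cat(sprintf("  admissions: %g total, %g surgical\n",
              x$total_admissions, x$surgical_admissions))
  cat(sprintf("  exams:      %g total, %g surgical\n",
              x$total_exams, x$surgical_exams))
  cat(sprintf("  patient-days: UICC %g, ICU %g\n",
              x$uicc_patient_days, x$icu_patient_days))
  if (length(x$surgeries_by_room) > 0) {
    cat("  surgeries by room:",
        paste(sprintf("%s=%g", names(x$surgeries_by_room), x$surgeries_by_room),
              collapse = ", "), "\n")
  } else {
    cat("  surgeries by room: none\n")
  }
  invisible(x)
}
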