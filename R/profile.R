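#' Median of consumption-note values
#'
#' The direct cost of a procedure's surgeries is summarised by the median
#' of its consumption-note totals (supplies and medicines spent during
#' surgery), which is robust to the occasional very expensive case; for an
#' even number of surgeries the mean of the two middle values is used.
#'
#' @param values Non-empty numeric vector of non-negative currency values.
#' @return The median, a single number.
#' @export
#' @examples
#' median_currency(c(100, 200, 300, 1000)) # 250; the mean would be 400
median_currency <- function(values) {
  if (length(values) == 0) {
    rlang::abort("no consumption-note values: the procedure has no encounters")
  }
  if (any(is.na(values)) || any(values < 0)) {
    rlang::abort("consumption-note values must be non-negative and non-missing")
  }
  stats::median(as.numeric(values))
}

#' Profile one surgical procedure
#'
#' Reduces the encounters of one procedure code to the drivers the cost
#' model consumes: the median direct (consumption-note) cost, the mean
#' length of stay at the UICC and ICU, the mean exam count, and the tally
#' of surgeries per operating room.
#'
#' @param encounters Data frame of surgical encounters with columns
#'   `procedure_code`, `room_id`, `direct_supplies_cost`, `los_uicc_days`,
#'   `los_icu_days`, `exam_count`. Rows with a `type` column keep only
#'   `type == "surgical"`.
#' @param procedure_code The procedure to profile.
#'
#' @return An object of class `procedure_profile` with fields
#'   `procedure_code`, `n`, `median_direct_cost`, `mean_los_uicc`,
#'   `mean_los_icu`, `mean_exam_count`, `room_counts`.
#' @export
profile_procedure <- function(encounters, procedure_code) {
  encounters <- tibble::as_tibble(encounters)
  if ("type" %in% names(encounters)) {
    encounters <- encounters[encounters$type == "surgical", , drop = FALSE]
  }
  needed <- c("procedure_code", "room_id", "direct_supplies_cost",
              "los_uicc_days", "los_icu_days", "exam_count")
  missing_cols <- setdiff(needed, names(encounters))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "encounters lack required columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  mine <- encounters[encounters$procedure_code == procedure_code, , drop = FALSE]
  if (nrow(mine) == 0) {
    available <- sort(unique(encounters$procedure_code))
    rlang::abort(paste0(
      "no encounters for procedure '", procedure_code, "'; available: ",
      if (length(available)) paste(available, collapse = ", ") else "(none)"
    ))
  }
  rooms <- table(mine$room_id)
  room_counts <- stats::setNames(as.numeric(rooms), names(rooms))
  room_counts <- room_counts[order(names(room_counts))]
  structure(
    list(
      procedure_code = procedure_code,
      n = nrow(mine),
      median_direct_cost = median_currency(mine$direct_supplies_cost),
      mean_los_uicc = mean(mine$los_uicc_days),
      mean_los_icu = mean(mine$los_icu_days),
      mean_exam_count = mean(mine$exam_count),
      room_counts = room_counts
    ),
    class = "procedure_profile"
  )
}

#' @export
print.procedure_profile <- function(x, ...) {
  cat("<procedure_profile>", x$procedure_code, sprintf("(n = %d)\n", x$n))
  cat(sprintf("  median direct cost: %g\n", x$median_direct_cost))
  cat(sprintf("  mean LOS: UICC %g d, ICU %g d; mean exams %g\n",
              x$mean_los_uicc, x$mean_los_icu, x$mean_exam_count))
  cat("  rooms:",
      paste(sprintf("%s=%g", names(x$room_counts), x$room_counts), collapse = ", "),
      "\n")
  invisible(x)
}
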