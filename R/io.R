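#' @title CSV schemas
#' @name surgicost_schemas
#' @description
#' Three delimited-text exports feed a costing run, UTF-8 with a header
#' row (comma/`.` by default; semicolon/`,` with `dialect = "br"`):
#'
#' * `ledger.csv`: `period, cost_center, room_id, resource, amount` — one
#'   absorbed monetary amount per (period, cost center, resource);
#'   `room_id` is blank except for per-room operating-room sub-centers.
#' * `encounters.csv`: `encounter_id, period, type, procedure_code,
#'   room_id, direct_supplies_cost, los_uicc_days, los_icu_days,
#'   exam_count` — one row per hospitalization; non-surgical rows
#'   (`type = "other"`) leave the procedure, room and direct-cost fields
#'   blank and feed only the activity denominators.
#' * `census.csv` (optional, else derived from encounters): the scalar
#'   denominators `period, total_admissions, surgical_admissions,
#'   total_exams, surgical_exams, uicc_patient_days, icu_patient_days`
#'   plus `room_id, surgeries`, one row per operating room with the
#'   scalars repeated.
#'
#' Blank numeric cells are validation errors, not zeros, so cost drivers
#' cannot be dropped silently. A file with any error produces no output:
#' the reader signals a condition of class `surgicost_validation_error`
#' carrying the full row-by-row report.
NULL

dialect_delim <- function(config) {
  if (config$dialect == "br") ";" else ","
}

parse_num <- function(x, config) {
  if (config$dialect == "br") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

fmt_num <- function(x, config) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  if (config$dialect == "br") out <- gsub(".", ",", out, fixed = TRUE)
  out
}

fmt_currency <- function(x, config) {
  d <- config$rounding_decimals
  out <- ifelse(is.na(x), "", formatC(round(x, d), format = "f", digits = d))
  if (config$dialect == "br") out <- gsub(".", ",", out, fixed = TRUE)
  out
}

new_validation_report <- function(errors, warnings) {
  structure(list(errors = errors, warnings = warnings),
            class = "surgicost_validation_report")
}

report_collector <- function() {
  errors <- list()
  warnings <- list()
  list(
    error = function(row, message) {
      errors[[length(errors) + 1]] <<- tibble::tibble(row = row, message = message)
    },
    warning = function(row, message) {
      warnings[[length(warnings) + 1]] <<- tibble::tibble(row = row, message = message)
    },
    build = function() {
      new_validation_report(
        errors = if (length(errors)) dplyr::bind_rows(errors) else
          tibble::tibble(row = integer(), message = character()),
        warnings = if (length(warnings)) dplyr::bind_rows(warnings) else
          tibble::tibble(row = integer(), message = character())
      )
    }
  )
}

#' @export
print.surgicost_validation_report <- function(x, ...) {
  cat("<validation report>", nrow(x$errors), "error(s),",
      nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors)) {
    for (i in seq_len(nrow(x$errors))) {
      cat(sprintf("  error   row %s: %s\n", x$errors$row[i], x$errors$message[i]))
    }
  }
  if (nrow(x$warnings)) {
    for (i in seq_len(nrow(x$warnings))) {
      cat(sprintf("  warning row %s: %s\n", x$warnings$row[i], x$warnings$message[i]))
    }
  }
  invisible(x)
}

#' Retrieve the validation report attached to a parsed table
#'
#' @param x A table returned by [read_ledger()], [read_encounters()] or
#'   [read_census()].
#' @return The `surgicost_validation_report` recorded while parsing.
#' @export
validation_report <- function(x) {
  attr(x, "validation_report")
}

finish_read <- function(data, report, what, path) {
  if (nrow(report$warnings) > 0) {
    for (i in seq_len(nrow(report$warnings))) {
      rlang::warn(paste0(what, " ", path, " row ", report$warnings$row[i],
                         ": ", report$warnings$message[i]))
    }
  }
  if (nrow(report$errors) > 0) {
    shown <- utils::head(report$errors, 10)
    rlang::abort(
      c(paste0(what, " ", path, " failed validation (",
               nrow(report$errors), " error(s)):"),
        sprintf("row %s: %s", shown$row, shown$message)),
      class = "surgicost_validation_error",
      report = report
    )
  }
  attr(data, "validation_report") <- report
  data
}

read_raw_csv <- function(path, required_cols, config, what) {
  if (!file.exists(path)) {
    rlang::abort(paste0(what, " file not found: ", path))
  }
  raw <- readr::read_delim(
    path, delim = dialect_delim(config),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  missing_cols <- setdiff(required_cols, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      what, " ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw
}

blank <- function(x) is.na(x) | x == ""

#' Read a cost-center ledger export
#'
#' Parses and validates `ledger.csv` (see [surgicost_schemas]); every
#' malformed row is reported with its row number, and any error aborts
#' with a `surgicost_validation_error` so that no cost output can be
#' produced from bad input.
#'
#' @param path Path to the CSV file.
#' @param config A [cost_config()]; sets the dialect, the per-room
#'   operating-room requirement and an optional expected period.
#' @return A tibble `period, cost_center, room_id, resource, amount` with
#'   the validation report attached (see [validation_report()]).
#' @export
read_ledger <- function(path, config = cost_config()) {
  cols <- c("period", "cost_center", "room_id", "resource", "amount")
  raw <- read_raw_csv(path, cols, config, "ledger")
  rep <- report_collector()
  amount <- parse_num(raw$amount, config)
  for (i in seq_len(nrow(raw))) {
    r <- i + 1L  # header is line 1
    if (blank(raw$period[i])) rep$error(r, "period is blank")
    if (!raw$cost_center[i] %in% cost_centers()) {
      rep$error(r, paste0("unknown cost_center '", raw$cost_center[i], "'"))
    }
    if (!raw$resource[i] %in% resource_categories()) {
      rep$error(r, paste0("unknown resource '", raw$resource[i], "'"))
    }
    if (blank(raw$amount[i]) || is.na(amount[i])) {
      rep$error(r, paste0("amount is not a number (got '", raw$amount[i], "')"))
    } else if (amount[i] < 0) {
      rep$error(r, paste0("amount must be non-negative (got '", raw$amount[i], "')"))
    }
    if (!blank(raw$room_id[i]) && raw$cost_center[i] != "OPERATING_ROOM") {
      rep$error(r, "room_id is only allowed on OPERATING_ROOM entries")
    }
    if (config$or_mode == "per_room" && identical(raw$cost_center[i], "OPERATING_ROOM") &&
        blank(raw$room_id[i])) {
      rep$error(r, "per-room mode requires a room_id on OPERATING_ROOM entries")
    }
    if (!is.null(config$period) && !blank(raw$period[i]) &&
        raw$period[i] != config$period) {
      rep$error(r, paste0("period '", raw$period[i], "' differs from configured '",
                          config$period, "'"))
    }
  }
  key <- paste(raw$period, raw$cost_center, raw$room_id, raw$resource)
  dup <- which(duplicated(key))
  for (i in dup) {
    rep$error(i + 1L, paste0("duplicate entry for (", raw$period[i], ", ",
                             raw$cost_center[i], ", ", raw$resource[i], ")"))
  }
  out <- tibble::tibble(
    period = raw$period,
    cost_center = raw$cost_center,
    room_id = ifelse(blank(raw$room_id), NA_character_, raw$room_id),
    resource = raw$resource,
    amount = amount
  )
  finish_read(out, rep$build(), "ledger", path)
}

#' Read a hospitalization-encounter export
#'
#' Parses and validates `encounters.csv` (see [surgicost_schemas]).
#' Surgical rows must carry a procedure code, an operating room and a
#' consumption-note direct cost; non-surgical rows must leave them blank
#' (populated fields are warnings) and contribute only to the activity
#' denominators. Exam counts must be whole numbers; lengths of stay may
#' be fractional.
#'
#' @inheritParams read_ledger
#' @return A tibble of all activity rows (surgical and other) in schema
#'   order, with the validation report attached.
#' @export
read_encounters <- function(path, config = cost_config()) {
  cols <- c("encounter_id", "period", "type", "procedure_code", "room_id",
            "direct_supplies_cost", "los_uicc_days", "los_icu_days", "exam_count")
  raw <- read_raw_csv(path, cols, config, "encounters")
  rep <- report_collector()
  direct <- parse_num(raw$direct_supplies_cost, config)
  uicc <- parse_num(raw$los_uicc_days, config)
  icu <- parse_num(raw$los_icu_days, config)
  exams <- parse_num(raw$exam_count, config)
  for (i in seq_len(nrow(raw))) {
    r <- i + 1L
    if (blank(raw$encounter_id[i])) rep$error(r, "encounter_id is blank")
    if (blank(raw$period[i])) rep$error(r, "period is blank")
    if (!is.null(config$period) && !blank(raw$period[i]) &&
        raw$period[i] != config$period) {
      rep$error(r, paste0("period '", raw$period[i], "' differs from configured '",
                          config$period, "'"))
    }
    if (!raw$type[i] %in% c("surgical", "other")) {
      rep$error(r, paste0("type must be 'surgical' or 'other' (got '",
                          raw$type[i], "')"))
      next
    }
    num_field <- function(value, parsed, name, required) {
      if (blank(value)) {
        if (required) rep$error(r, paste0(name, " is blank"))
        return(invisible(NULL))
      }
      if (is.na(parsed)) {
        rep$error(r, paste0(name, " is not a number (got '", value, "')"))
      } else if (parsed < 0) {
        rep$error(r, paste0(name, " must be non-negative (got '", value, "')"))
      }
    }
    num_field(raw$los_uicc_days[i], uicc[i], "los_uicc_days", TRUE)
    num_field(raw$los_icu_days[i], icu[i], "los_icu_days", TRUE)
    num_field(raw$exam_count[i], exams[i], "exam_count", TRUE)
    if (!blank(raw$exam_count[i]) && !is.na(exams[i]) &&
        exams[i] != as.integer(exams[i])) {
      rep$error(r, paste0("exam_count must be an integer (got '",
                          raw$exam_count[i], "')"))
    }
    if (raw$type[i] == "surgical") {
      if (blank(raw$procedure_code[i])) rep$error(r, "surgical row lacks procedure_code")
      if (blank(raw$room_id[i])) rep$error(r, "surgical row lacks room_id")
      num_field(raw$direct_supplies_cost[i], direct[i], "direct_supplies_cost", TRUE)
    } else {
      if (!blank(raw$procedure_code[i])) {
        rep$warning(r, "non-surgical row has a procedure_code; ignored")
      }
      if (!blank(raw$room_id[i])) {
        rep$warning(r, "non-surgical row has a room_id; ignored")
      }
      if (!blank(raw$direct_supplies_cost[i])) {
        rep$warning(r, "non-surgical row has a direct_supplies_cost; ignored")
      }
    }
  }
  dup <- which(duplicated(raw$encounter_id) & !blank(raw$encounter_id))
  for (i in dup) {
    rep$error(i + 1L, paste0("duplicate encounter_id '", raw$encounter_id[i], "'"))
  }
  is_surg <- raw$type == "surgical"
  out <- tibble::tibble(
    encounter_id = raw$encounter_id,
    period = raw$period,
    type = raw$type,
    procedure_code = ifelse(is_surg & !blank(raw$procedure_code),
                            raw$procedure_code, NA_character_),
    room_id = ifelse(is_surg & !blank(raw$room_id), raw$room_id, NA_character_),
    direct_supplies_cost = ifelse(is_surg, direct, NA_real_),
    los_uicc_days = uicc,
    los_icu_days = icu,
    exam_count = as.integer(exams)
  )
  finish_read(out, rep$build(), "encounters", path)
}

#' Read an activity census export
#'
#' Parses `census.csv` (see [surgicost_schemas]): the scalar denominators
#' must be identical on every row; rooms are collected from the
#' `room_id, surgeries` columns.
#'
#' @inheritParams read_ledger
#' @return A [hospital_census()] with the validation report attached.
#' @export
read_census <- function(path, config = cost_config()) {
  cols <- c("period", "total_admissions", "surgical_admissions", "total_exams",
            "surgical_exams", "uicc_patient_days", "icu_patient_days",
            "room_id", "surgeries")
  raw <- read_raw_csv(path, cols, config, "census")
  rep <- report_collector()
  if (nrow(raw) == 0) {
    rlang::abort(paste0("census ", path, " has no rows"))
  }
  scalars <- c("period", "total_admissions", "surgical_admissions",
               "total_exams", "surgical_exams", "uicc_patient_days",
               "icu_patient_days")
  for (col in scalars) {
    if (length(unique(raw[[col]])) > 1) {
      rep$error(2L, paste0("column ", col, " must be identical on every census row"))
    }
    if (blank(raw[[col]][1])) rep$error(2L, paste0(col, " is blank"))
  }
  numeric_scalar <- function(col) {
    v <- parse_num(raw[[col]][1], config)
    if (is.na(v) || v < 0) {
      rep$error(2L, paste0(col, " is not a non-negative number (got '",
                           raw[[col]][1], "')"))
      return(0)
    }
    v
  }
  vals <- stats::setNames(
    lapply(scalars[-1], numeric_scalar),
    scalars[-1]
  )
  surgeries <- parse_num(raw$surgeries, config)
  rooms <- character(0)
  counts <- numeric(0)
  for (i in seq_len(nrow(raw))) {
    if (blank(raw$room_id[i])) {
      if (!blank(raw$surgeries[i])) {
        rep$error(i + 1L, "surgeries given without a room_id")
      }
      next
    }
    if (blank(raw$surgeries[i]) || is.na(surgeries[i]) || surgeries[i] < 0) {
      rep$error(i + 1L, paste0("surgeries for room ", raw$room_id[i],
                               " is not a non-negative number"))
      next
    }
    if (raw$room_id[i] %in% rooms) {
      rep$error(i + 1L, paste0("duplicate census row for room ", raw$room_id[i]))
      next
    }
    rooms <- c(rooms, raw$room_id[i])
    counts <- c(counts, surgeries[i])
  }
  report <- rep$build()
  if (nrow(report$errors) == 0) {
    census <- hospital_census(
      period = raw$period[1],
      total_admissions = vals$total_admissions,
      surgical_admissions = vals$surgical_admissions,
      total_exams = vals$total_exams,
      surgical_exams = vals$surgical_exams,
      uicc_patient_days = vals$uicc_patient_days,
      icu_patient_days = vals$icu_patient_days,
      surgeries_by_room = stats::setNames(counts, rooms)
    )
    finish_read(census, report, "census", path)
  } else {
    finish_read(NULL, report, "census", path)
  }
}

write_csv_plain <- function(df, path, config) {
  readr::write_delim(df, path, delim = dialect_delim(config), na = "")
}

#' Write a ledger, encounter or census table in schema order
#'
#' Companions to the readers, used to materialize synthetic fixtures and
#' intermediate results; numeric cells are written with full precision so
#' that a read-back reproduces the values.
#'
#' @param ledger,activity,census The object to write.
#' @param path Output CSV path.
#' @param config A [cost_config()] (controls the dialect).
#' @return The path, invisibly.
#' @export
write_ledger <- function(ledger, path, config = cost_config()) {
  ledger <- as_ledger_tbl(ledger)
  out <- tibble::tibble(
    period = ledger$period,
    cost_center = ledger$cost_center,
    room_id = ifelse(is.na(ledger$room_id), "", ledger$room_id),
    resource = ledger$resource,
    amount = fmt_num(ledger$amount, config)
  )
  write_csv_plain(out, path, config)
  invisible(path)
}

#' @rdname write_ledger
#' @export
write_encounters <- function(activity, path, config = cost_config()) {
  activity <- tibble::as_tibble(activity)
  out <- tibble::tibble(
    encounter_id = activity$encounter_id,
    period = activity$period,
    type = activity$type,
    procedure_code = ifelse(is.na(activity$procedure_code), "",
                            activity$procedure_code),
    room_id = ifelse(is.na(activity$room_id), "", activity$room_id),
    direct_supplies_cost = fmt_num(activity$direct_supplies_cost, config),
    los_uicc_days = fmt_num(activity$los_uicc_days, config),
    los_icu_days = fmt_num(activity$los_icu_days, config),
    exam_count = fmt_num(as.numeric(activity$exam_count), config)
  )
  write_csv_plain(out, path, config)
  invisible(path)
}

#' @rdname write_ledger
#' @export
write_census <- function(census, path, config = cost_config()) {
  stopifnot(inherits(census, "hospital_census"))
  rooms <- names(census$surgeries_by_room)
  n <- max(1L, length(rooms))
  out <- tibble::tibble(
    period = rep(census$period, n),
    total_admissions = fmt_num(rep(census$total_admissions, n), config),
    surgical_admissions = fmt_num(rep(census$surgical_admissions, n), config),
    total_exams = fmt_num(rep(census$total_exams, n), config),
    surgical_exams = fmt_num(rep(census$surgical_exams, n), config),
    uicc_patient_days = fmt_num(rep(census$uicc_patient_days, n), config),
    icu_patient_days = fmt_num(rep(census$icu_patient_days, n), config),
    room_id = if (length(rooms)) rooms else "",
    surgeries = if (length(rooms)) {
      fmt_num(unname(census$surgeries_by_room), config)
    } else {
      ""
    }
  )
  write_csv_plain(out, path, config)
  invisible(path)
}

#' Write the per-procedure cost report
#'
#' One row per procedure, sorted by code, with exactly the breakdown
#' columns in declared order; values are rounded half-even to
#' `config$rounding_decimals` and written with a fixed number of decimals
#' (e.g. `472.50`), so a re-read reproduces the rounded values exactly.
#' When `schedule` is given, a companion `<path stem>_rates.csv` with the
#' unit-cost schedule is written alongside.
#'
#' @param breakdowns A `cost_breakdown` tibble from
#'   [cost_all_procedures()] (or a single-procedure breakdown).
#' @param path Output CSV path.
#' @param config A [cost_config()].
#' @param schedule Optional `unit_cost_schedule` for the companion file.
#' @return The path, invisibly; warns and writes a header-only file when
#'   `breakdowns` has no rows.
#' @export
write_cost_report <- function(breakdowns, path, config = cost_config(),
                              schedule = NULL) {
  breakdowns <- tibble::as_tibble(breakdowns)
  if (nrow(breakdowns) == 0) {
    rlang::warn(paste0("no procedures to report; writing header-only ", path))
  }
  breakdowns <- breakdowns[order(breakdowns$procedure_code), , drop = FALSE]
  out <- breakdowns
  for (col in setdiff(names(out), "procedure_code")) {
    out[[col]] <- fmt_currency(breakdowns[[col]], config)
  }
  write_csv_plain(out, path, config)
  if (!is.null(schedule)) {
    rates_path <- sub("(\\.[^.]*)?$", "_rates\\1", path)
    write_rate_schedule(schedule, rates_path, config)
  }
  invisible(path)
}

#' Write a unit-cost schedule as CSV
#'
#' Long format, one row per rate component (`uicc_daily`, `icu_daily`,
#' `exam_unit`, `nir_admission`, and `or_per_surgery` per room) with
#' non-personnel and personnel columns, rounded like the cost report.
#'
#' @param schedule A `unit_cost_schedule`.
#' @param path Output CSV path.
#' @param config A [cost_config()].
#' @return The path, invisibly.
#' @export
write_rate_schedule <- function(schedule, path, config = cost_config()) {
  tab <- rate_table(schedule)
  out <- tibble::tibble(
    component = tab$component,
    room_id = ifelse(is.na(tab$room_id), "", tab$room_id),
    non_personnel = fmt_currency(tab$non_personnel, config),
    personnel = fmt_currency(tab$personnel, config)
  )
  write_csv_plain(out, path, config)
  invisible(path)
}
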