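#' Costing run configuration
#'
#' Collects the knobs that resolve choices the costing model leaves open:
#' how operating-room indirect cost is apportioned, how exam cost reaches a
#' procedure, which resource categories count as personnel, and how report
#' values are rounded.
#'
#' @param or_mode `"pooled"` (default) treats the surgical center as one
#'   ledger cost center and splits its total by the proportion of surgeries
#'   in each operating room, which collapses to a single uniform
#'   per-surgery rate; `"per_room"` expects one ledger sub-center per
#'   `room_id` and divides each room's total by that room's surgery count.
#' @param exam_mode `"per_exam"` (default) charges each procedure its mean
#'   exam count times the hospital-wide per-exam rate; `"flat_share"` is
#'   the literal aggregate reading — the surgical share of the exam-center
#'   total divided evenly over surgical admissions, identical for every
#'   procedure. Both allocate the same surgical total in aggregate.
#' @param personnel_categories Resource categories treated as personnel
#'   when splitting ledger entries; must be a subset of
#'   [resource_categories()]. Default `"Personnel"`.
#' @param rounding_decimals Non-negative integer; decimals kept (half-even)
#'   when writing reports. Internal arithmetic is never rounded.
#' @param dialect CSV dialect: `"standard"` (comma separator, `.` decimal)
#'   or `"br"` (semicolon separator, `,` decimal) for Brazilian exports.
#' @param period Optional period identifier; when set, readers require all
#'   rows to carry it.
#'
#' @return An object of class `surgicost_config`.
#' @export
#' @examples
#' cost_config(or_mode = "per_room", rounding_decimals = 0)
cost_config <- function(or_mode = c("pooled", "per_room"),
                        exam_mode = c("per_exam", "flat_share"),
                        personnel_categories = "Personnel",
                        rounding_decimals = 2L,
                        dialect = c("standard", "br"),
                        period = NULL) {
  or_mode <- match.arg(or_mode)
  exam_mode <- match.arg(exam_mode)
  dialect <- match.arg(dialect)
  bad <- setdiff(personnel_categories, resource_categories())
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "personnel_categories must be canonical resource categories; unknown: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (length(personnel_categories) < 1) {
    rlang::abort("at least one personnel category is required")
  }
  if (!is.numeric(rounding_decimals) || length(rounding_decimals) != 1 ||
      is.na(rounding_decimals) || rounding_decimals < 0 ||
      rounding_decimals != as.integer(rounding_decimals)) {
    rlang::abort("rounding_decimals must be a single non-negative integer")
  }
  structure(
    list(
      or_mode = or_mode,
      exam_mode = exam_mode,
      personnel_categories = personnel_categories,
      rounding_decimals = as.integer(rounding_decimals),
      dialect = dialect,
      period = period
    ),
    class = "surgicost_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys: `or_mode`, `exam_mode`, `personnel_categories`,
#' `rounding_decimals`, `dialect`, `period`. Missing keys fall back to the
#' [cost_config()] defaults; unknown keys are an error so that typos do not
#' silently revert to defaults.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @return A `surgicost_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("or_mode", "exam_mode", "personnel_categories",
             "rounding_decimals", "dialect", "period")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "unknown config keys in ", path, ": ", paste(unknown, collapse = ", ")
    ))
  }
  defaults <- cost_config()
  args <- utils::modifyList(
    defaults[known][!vapply(defaults[known], is.null, logical(1))],
    raw
  )
  do.call(cost_config, args)
}

#' @export
print.surgicost_config <- function(x, ...) {
  cat("<surgicost_config>\n")
  cat("  or_mode:            ", x$or_mode, "\n")
  cat("  exam_mode:          ", x$exam_mode, "\n")
  cat("  personnel_categories:", paste(x$personnel_categories, collapse = ", "), "\n")
  cat("  rounding_decimals:  ", x$rounding_decimals, "\n")
  cat("  dialect:            ", x$dialect, "\n")
  if (!is.null(x$period)) cat("  period:             ", x$period, "\n")
  invisible(x)
}
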