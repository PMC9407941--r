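#' Parameters for a synthetic hospital
#'
#' Describes a simulated accounting period: how many procedures and
#' surgeries to draw, the per-procedure distributions of the cost drivers
#' (length of stay, exams, consumption-note direct cost, operating-room
#' assignment), the non-surgical activity that pads the hospital-wide
#' denominators, and the ground-truth unit rates from which the ledger is
#' constructed. Each distribution list may carry `fixed = v` to collapse
#' it to a point mass, which reduces the simulation to a hand-checkable
#' case.
#'
#' Stay lengths are drawn from rounded lognormals (hospital stays are
#' right-skewed, whole days), exam counts from a Poisson, direct costs
#' from a lognormal; the defaults are plausible round figures for a
#' mid-size public hospital in local currency, not a calibration to any
#' real institution.
#'
#' @param seed Integer seed; a single seeded generator drives all draws.
#' @param period Period identifier stamped on every row.
#' @param n_procedures Number of distinct procedure codes (>= 1).
#' @param surgeries_per_procedure `list(min, lambda)`: per-procedure count
#'   `min + Poisson(lambda)`; or `list(fixed = n)`.
#' @param n_other_admissions Non-surgical hospitalizations (>= 0).
#' @param los_uicc_dist `list(meanlog, sdlog)` for ward days, rounded, at
#'   least 1 day; a per-procedure jitter of `+/- 0.3` is applied to
#'   `meanlog`; or `list(fixed = d)`.
#' @param los_icu_dist As above plus `p_zero_range`, the range of the
#'   per-procedure probability that a surgery never enters the ICU.
#' @param exam_dist `list(lambda_range)`: per-procedure Poisson rate drawn
#'   uniformly; or `list(fixed = k)`.
#' @param direct_cost_dist `list(meanlog_range, sdlog)` lognormal
#'   consumption-note cost, rounded to centavos; or `list(fixed = v)`.
#' @param other_exam_lambda Poisson rate of exams for non-surgical
#'   admissions.
#' @param other_icu `list(p, meanlog, sdlog)`: non-surgical ICU use.
#' @param rooms Named probability vector of operating-room assignment;
#'   normalized to sum to 1.
#' @param true_rates Named list of ground-truth unit rates: `uicc_daily`,
#'   `icu_daily`, `exam_unit`, `nir_admission`, `or_per_surgery` (scalar,
#'   or named per room), and the five `_pers` personnel counterparts.
#' @param noise_mode `"exact"` constructs every ledger total as
#'   `true rate x realized denominator`; `"perturbed"` multiplies each
#'   ledger amount by `exp(N(0, noise_sd))`, emulating costs that the
#'   rates do not fully explain.
#' @param noise_sd Perturbation scale on the log scale.
#' @param or_mode Ledger layout for the surgical center: one pooled cost
#'   center or one sub-center per room.
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              period = "2022-01",
                              n_procedures = 10L,
                              surgeries_per_procedure = list(min = 3, lambda = 9),
                              n_other_admissions = 150L,
                              los_uicc_dist = list(meanlog = 1.1, sdlog = 0.5),
                              los_icu_dist = list(meanlog = 0.7, sdlog = 0.5,
                                                  p_zero_range = c(0.5, 0.95)),
                              exam_dist = list(lambda_range = c(2, 12)),
                              direct_cost_dist = list(meanlog_range = log(c(800, 5000)),
                                                      sdlog = 0.35),
                              other_exam_lambda = 4,
                              other_icu = list(p = 0.1, meanlog = 0.9, sdlog = 0.5),
                              rooms = c(R1 = 0.4, R2 = 0.35, R3 = 0.25),
                              true_rates = list(
                                uicc_daily = 150, icu_daily = 900,
                                exam_unit = 25, nir_admission = 40,
                                or_per_surgery = 600,
                                uicc_daily_pers = 250, icu_daily_pers = 1400,
                                exam_unit_pers = 15, nir_admission_pers = 60,
                                or_per_surgery_pers = 1100
                              ),
                              noise_mode = c("exact", "perturbed"),
                              noise_sd = 0.05,
                              or_mode = c("pooled", "per_room")) {
  noise_mode <- match.arg(noise_mode)
  or_mode <- match.arg(or_mode)
  if (n_procedures < 1) rlang::abort("n_procedures must be >= 1")
  if (n_other_admissions < 0) rlang::abort("n_other_admissions must be >= 0")
  if (length(rooms) < 1 || is.null(names(rooms)) || any(rooms < 0) ||
      sum(rooms) <= 0) {
    rlang::abort("rooms must be a named non-negative probability vector")
  }
  rooms <- rooms / sum(rooms)
  needed <- c("uicc_daily", "icu_daily", "exam_unit", "nir_admission",
              "or_per_surgery", "uicc_daily_pers", "icu_daily_pers",
              "exam_unit_pers", "nir_admission_pers", "or_per_surgery_pers")
  missing_rates <- setdiff(needed, names(true_rates))
  if (length(missing_rates) > 0) {
    rlang::abort(paste0("true_rates lacks: ", paste(missing_rates, collapse = ", ")))
  }
  if (any(unlist(true_rates) < 0)) rlang::abort("true rates must be non-negative")
  structure(
    list(
      seed = as.integer(seed), period = period,
      n_procedures = as.integer(n_procedures),
      surgeries_per_procedure = surgeries_per_procedure,
      n_other_admissions = as.integer(n_other_admissions),
      los_uicc_dist = los_uicc_dist, los_icu_dist = los_icu_dist,
      exam_dist = exam_dist, direct_cost_dist = direct_cost_dist,
      other_exam_lambda = other_exam_lambda, other_icu = other_icu,
      rooms = rooms, true_rates = true_rates,
      noise_mode = noise_mode, noise_sd = noise_sd, or_mode = or_mode
    ),
    class = "simulation_params"
  )
}

# Expand a scalar-or-named-per-room true rate over the census rooms.
expand_room_rate <- function(rate, rooms) {
  if (length(rate) == 1 && is.null(names(rate))) {
    return(stats::setNames(rep(as.numeric(rate), length(rooms)), rooms))
  }
  missing_rooms <- setdiff(rooms, names(rate))
  if (length(missing_rooms) > 0) {
    rlang::abort(paste0("true OR rate lacks room(s): ",
                        paste(missing_rooms, collapse = ", ")))
  }
  vapply(rooms, function(r) as.numeric(rate[[r]]), numeric(1))
}

truth_schedule <- function(true_rates, census, config) {
  rooms <- names(census$surgeries_by_room)
  structure(
    list(
      period = census$period,
      uicc_daily = true_rates$uicc_daily,
      icu_daily = true_rates$icu_daily,
      exam_unit = true_rates$exam_unit,
      nir_admission = true_rates$nir_admission,
      or_indirect_per_surgery = expand_room_rate(true_rates$or_per_surgery, rooms),
      uicc_daily_pers = true_rates$uicc_daily_pers,
      icu_daily_pers = true_rates$icu_daily_pers,
      exam_unit_pers = true_rates$exam_unit_pers,
      nir_admission_pers = true_rates$nir_admission_pers,
      or_per_surgery_pers = expand_room_rate(true_rates$or_per_surgery_pers, rooms),
      census = census,
      config = config
    ),
    class = "unit_cost_schedule"
  )
}

# Bottom-up accumulation: price each encounter individually at the unit
# rates, then take the median direct cost and the mean of every indirect
# component per procedure. By linearity this must agree with the top-down
# engine; it serves as the ground-truth oracle for synthetic hospitals.
bottom_up_breakdowns <- function(surgical, schedule) {
  codes <- sort(unique(surgical$procedure_code))
  rows <- lapply(codes, function(code) {
    e <- surgical[surgical$procedure_code == code, , drop = FALSE]
    or_np <- schedule$or_indirect_per_surgery[e$room_id]
    or_p <- schedule$or_per_surgery_pers[e$room_id]
    exams_np <- exam_component(
      structure(list(mean_exam_count = mean(e$exam_count)), class = "procedure_profile"),
      schedule, schedule$exam_unit
    )
    exams_p <- exam_component(
      structure(list(mean_exam_count = mean(e$exam_count)), class = "procedure_profile"),
      schedule, schedule$exam_unit_pers
    )
    or_direct <- median_currency(e$direct_supplies_cost)
    or_indirect <- mean(or_np)
    hosp_uicc <- mean(schedule$uicc_daily * e$los_uicc_days)
    hosp_icu <- mean(schedule$icu_daily * e$los_icu_days)
    hosp_nir <- schedule$nir_admission
    pers_or <- mean(or_p)
    pers_uicc <- mean(schedule$uicc_daily_pers * e$los_uicc_days)
    pers_icu <- mean(schedule$icu_daily_pers * e$los_icu_days)
    pers_nir <- schedule$nir_admission_pers
    hospitalization_cost <- hosp_uicc + hosp_icu + exams_np + hosp_nir
    personnel_cost <- pers_or + pers_uicc + pers_icu + exams_p + pers_nir
    tibble::tibble(
      procedure_code = code,
      or_direct = or_direct, or_indirect = or_indirect,
      operating_room_cost = or_direct + or_indirect,
      hosp_uicc = hosp_uicc, hosp_icu = hosp_icu, hosp_exams = exams_np,
      hosp_nir = hosp_nir, hospitalization_cost = hospitalization_cost,
      pers_or = pers_or, pers_uicc = pers_uicc, pers_icu = pers_icu,
      pers_exams = exams_p, pers_nir = pers_nir,
      personnel_cost = personnel_cost,
      total = (or_direct + or_indirect) + hospitalization_cost + personnel_cost
    )
  })
  dplyr::bind_rows(rows)
}

draw_pos_days <- function(n, dist, meanlog_shift = 0) {
  if (!is.null(dist$fixed)) return(rep(dist$fixed, n))
  pmax(1, round(stats::rlnorm(n, dist$meanlog + meanlog_shift, dist$sdlog)))
}

#' Simulate a hospital accounting period
#'
#' Draws encounter-level drivers per procedure, aggregates the realized
#' denominators into a census, and constructs the cost-center ledger from
#' the ground-truth unit rates (`total = rate x realized denominator` in
#' exact mode, multiplicatively perturbed otherwise). Non-personnel center
#' totals are split across randomly chosen resource categories so the
#' ledger looks like a real absorption-costing export. The expected
#' per-procedure breakdowns are computed with an independent bottom-up
#' accumulation (price each encounter, then aggregate), not with the
#' top-down engine under test.
#'
#' @param params A [simulation_params()].
#' @return An object of class `synthetic_hospital`: `activity` (all
#'   hospitalizations), `encounters` (surgical rows), `census`, `ledger`,
#'   and `truth` (`$rates`, a `unit_cost_schedule`, and `$breakdowns`).
#'   Deterministic for a fixed seed.
#' @export
simulate_hospital <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  withr::with_seed(params$seed, {
    np <- params$n_procedures
    codes <- sprintf("P%03d", seq_len(np))
    spp <- params$surgeries_per_procedure
    n_j <- if (!is.null(spp$fixed)) {
      rep(as.integer(spp$fixed), np)
    } else {
      spp$min + stats::rpois(np, spp$lambda)
    }
    if (any(n_j < 1)) n_j[n_j < 1] <- 1L

    uicc_shift <- if (is.null(params$los_uicc_dist$fixed)) {
      stats::runif(np, -0.3, 0.3)
    } else {
      numeric(np)
    }
    icu_shift <- if (is.null(params$los_icu_dist$fixed)) {
      stats::runif(np, -0.3, 0.3)
    } else {
      numeric(np)
    }
    p_zero <- if (!is.null(params$los_icu_dist$fixed)) {
      numeric(np)
    } else {
      rng <- params$los_icu_dist$p_zero_range
      stats::runif(np, rng[1], rng[2])
    }
    exam_lambda <- if (!is.null(params$exam_dist$fixed)) {
      numeric(np)
    } else {
      rng <- params$exam_dist$lambda_range
      stats::runif(np, rng[1], rng[2])
    }
    direct_meanlog <- if (!is.null(params$direct_cost_dist$fixed)) {
      numeric(np)
    } else {
      rng <- params$direct_cost_dist$meanlog_range
      stats::runif(np, rng[1], rng[2])
    }

    surgical <- dplyr::bind_rows(lapply(seq_len(np), function(j) {
      n <- n_j[j]
      los_icu <- if (!is.null(params$los_icu_dist$fixed)) {
        rep(params$los_icu_dist$fixed, n)
      } else {
        zero <- stats::runif(n) < p_zero[j]
        days <- draw_pos_days(n, params$los_icu_dist, icu_shift[j])
        ifelse(zero, 0, days)
      }
      exams <- if (!is.null(params$exam_dist$fixed)) {
        rep(as.integer(params$exam_dist$fixed), n)
      } else {
        stats::rpois(n, exam_lambda[j])
      }
      direct <- if (!is.null(params$direct_cost_dist$fixed)) {
        rep(params$direct_cost_dist$fixed, n)
      } else {
        round(stats::rlnorm(n, direct_meanlog[j], params$direct_cost_dist$sdlog), 2)
      }
      tibble::tibble(
        type = "surgical",
        procedure_code = codes[j],
        room_id = sample(names(params$rooms), n, replace = TRUE,
                         prob = params$rooms),
        direct_supplies_cost = direct,
        los_uicc_days = as.numeric(draw_pos_days(n, params$los_uicc_dist,
                                                 uicc_shift[j])),
        los_icu_days = as.numeric(los_icu),
        exam_count = as.integer(exams)
      )
    }))

    n_other <- params$n_other_admissions
    other <- if (n_other > 0) {
      oi <- params$other_icu
      icu_use <- stats::runif(n_other) < oi$p
      tibble::tibble(
        type = "other",
        procedure_code = NA_character_,
        room_id = NA_character_,
        direct_supplies_cost = NA_real_,
        los_uicc_days = 0,
        los_icu_days = ifelse(
          icu_use,
          pmax(1, round(stats::rlnorm(n_other, oi$meanlog, oi$sdlog))),
          0
        ),
        exam_count = as.integer(stats::rpois(n_other, params$other_exam_lambda))
      )
    } else {
      NULL
    }

    activity <- dplyr::bind_rows(surgical, other)
    activity <- tibble::tibble(
      encounter_id = sprintf("E%05d", seq_len(nrow(activity))),
      period = params$period,
      activity
    )
    census <- build_census(activity)

    config <- cost_config(or_mode = params$or_mode, period = params$period)
    truth_rates <- truth_schedule(params$true_rates, census, config)
    check_positive_denominators(truth_rates, census)

    ledger <- build_truth_ledger(truth_rates, census, params)
    surgical_rows <- activity[activity$type == "surgical", , drop = FALSE]
    truth_breakdowns <- bottom_up_breakdowns(surgical_rows, truth_rates)

    structure(
      list(
        params = params,
        activity = activity,
        encounters = surgical_rows,
        census = census,
        ledger = ledger,
        truth = list(rates = truth_rates, breakdowns = truth_breakdowns)
      ),
      class = "synthetic_hospital"
    )
  })
}

check_positive_denominators <- function(rates, census) {
  checks <- list(
    list(rates$uicc_daily + rates$uicc_daily_pers, census$uicc_patient_days, "UICC patient-days"),
    list(rates$icu_daily + rates$icu_daily_pers, census$icu_patient_days, "ICU patient-days"),
    list(rates$exam_unit + rates$exam_unit_pers, census$total_exams, "exam count"),
    list(rates$nir_admission + rates$nir_admission_pers, census$total_admissions, "admissions"),
    list(sum(rates$or_indirect_per_surgery) + sum(rates$or_per_surgery_pers),
         sum(census$surgeries_by_room), "surgeries")
  )
  for (ch in checks) {
    if (ch[[1]] > 0 && ch[[2]] <= 0) {
      rlang::abort(paste0(
        "simulation produced zero ", ch[[3]],
        " while the corresponding true rate is positive; ",
        "the ledger total could not be absorbed"
      ))
    }
  }
}

# Split a center total across randomly chosen non-personnel resource
# categories; the last share is assigned by difference so the amounts sum
# back to the total.
split_resources <- function(total, k_max = 5) {
  cats <- setdiff(resource_categories(), "Personnel")
  k <- sample(2:k_max, 1)
  chosen <- sample(cats, k)
  w <- stats::runif(k, 0.5, 1.5)
  w <- w / sum(w)
  amounts <- total * w
  amounts[k] <- total - sum(amounts[-k])
  tibble::tibble(resource = chosen, amount = amounts)
}

build_truth_ledger <- function(rates, census, params) {
  rows <- list()
  add_center <- function(center, room_id, total_np, total_pers) {
    if (total_np > 0) {
      split <- split_resources(total_np)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        period = params$period, cost_center = center, room_id = room_id,
        resource = split$resource, amount = split$amount
      )
    }
    if (total_pers > 0) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        period = params$period, cost_center = center, room_id = room_id,
        resource = "Personnel", amount = total_pers
      )
    }
  }
  add_center("UICC", NA_character_,
             rates$uicc_daily * census$uicc_patient_days,
             rates$uicc_daily_pers * census$uicc_patient_days)
  add_center("ICU", NA_character_,
             rates$icu_daily * census$icu_patient_days,
             rates$icu_daily_pers * census$icu_patient_days)
  add_center("EXAMS", NA_character_,
             rates$exam_unit * census$total_exams,
             rates$exam_unit_pers * census$total_exams)
  add_center("NIR", NA_character_,
             rates$nir_admission * census$total_admissions,
             rates$nir_admission_pers * census$total_admissions)
  if (params$or_mode == "per_room") {
    for (r in names(census$surgeries_by_room)) {
      add_center("OPERATING_ROOM", r,
                 rates$or_indirect_per_surgery[[r]] * census$surgeries_by_room[[r]],
                 rates$or_per_surgery_pers[[r]] * census$surgeries_by_room[[r]])
    }
  } else {
    add_center("OPERATING_ROOM", NA_character_,
               sum(rates$or_indirect_per_surgery * census$surgeries_by_room),
               sum(rates$or_per_surgery_pers * census$surgeries_by_room))
  }
  ledger <- dplyr::bind_rows(rows)
  if (params$noise_mode == "perturbed" && nrow(ledger) > 0) {
    ledger$amount <- ledger$amount *
      exp(stats::rnorm(nrow(ledger), 0, params$noise_sd))
  }
  ledger
}

#' Write a synthetic hospital as CSV fixtures
#'
#' Emits `ledger.csv`, `encounters.csv` (all activity rows), `census.csv`
#' and `truth.csv` (the ground-truth rate table, full precision) in the
#' package CSV schemas, so a run of the engine — or of the command-line
#' `compute` — on the files can be compared against the truth.
#'
#' @param hospital A [simulate_hospital()] result.
#' @param dir Output directory (created if needed).
#' @param config A [cost_config()] controlling the dialect.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(hospital, dir, config = cost_config()) {
  stopifnot(inherits(hospital, "synthetic_hospital"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ledger(hospital$ledger, file.path(dir, "ledger.csv"), config)
  write_encounters(hospital$activity, file.path(dir, "encounters.csv"), config)
  write_census(hospital$census, file.path(dir, "census.csv"), config)
  tab <- rate_table(hospital$truth$rates)
  truth <- tibble::tibble(
    component = tab$component,
    room_id = ifelse(is.na(tab$room_id), "", tab$room_id),
    non_personnel = fmt_num(tab$non_personnel, config),
    personnel = fmt_num(tab$personnel, config)
  )
  write_csv_plain(truth, file.path(dir, "truth.csv"), config)
  invisible(dir)
}

#' @export
print.synthetic_hospital <- function(x, ...) {
  cat("<synthetic_hospital> period", x$census$period, "\n")
  cat(sprintf("  %d surgical encounters over %d procedures, %d other admissions\n",
              nrow(x$encounters),
              length(unique(x$encounters$procedure_code)),
              sum(x$activity$type == "other")))
  cat(sprintf("  ledger: %d entries, noise_mode %s\n",
              nrow(x$ledger), x$params$noise_mode))
  invisible(x)
}
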