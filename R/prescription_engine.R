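# The closed-loop prescription engine: daily prescription generation,
# weekly compliance gating, target-zone re-personalization, optional-day
# logic and the week-12 field-test override.

#' Construct a participant profile
#'
#' @param user_id participant identifier (<= 8 characters).
#' @param sex "M" or "F" (selects the TRIMP scaling coefficient).
#' @param baseline_hrrest baseline resting heart rate in bpm from the
#'   pre-intervention measurement days, or `NA` when no baseline exists.
#' @param hrmax maximum heart rate in bpm (a fixed per-participant input).
#' @param start_date calendar date of intervention day 1.
#' @param account_date date the account was created (used only for the
#'   milestone notification); defaults to one week before `start_date`.
#' @return object of class `participant_profile`.
#' @export
participant_profile <- function(user_id, sex, baseline_hrrest, hrmax,
                                start_date,
                                account_date = as.Date(start_date) - 7) {
  fl_assert(sex %in% c("M", "F"), "fitloop_validation_error",
            "sex must be 'M' or 'F'")
  fl_assert(hrmax >= 100 && hrmax <= 220, "fitloop_validation_error",
            "hrmax must be in 100..220 bpm")
  if (!is.na(baseline_hrrest)) {
    fl_assert(baseline_hrrest >= 30 && baseline_hrrest <= 120,
              "fitloop_validation_error",
              "baseline_hrrest must be in 30..120 bpm")
    fl_assert(baseline_hrrest < hrmax, "fitloop_validation_error",
              "baseline_hrrest must be below hrmax")
  }
  structure(list(
    user_id = user_id,
    sex = sex,
    baseline_hrrest = baseline_hrrest,
    hrmax = hrmax,
    start_date = as.Date(start_date),
    account_date = as.Date(account_date)
  ), class = "participant_profile")
}

#' Karvonen (heart-rate-reserve) target zone
#'
#' Target HR = HRrest + (percent intensity / 100) * (HRmax - HRrest),
#' evaluated at both ends of the intensity band and rounded half-up to
#' integer bpm (the monitor's feedback operates on integer bpm).
#'
#' @param hrrest resting heart rate, bpm.
#' @param hrmax maximum heart rate, bpm (must exceed `hrrest`).
#' @param pct_lo,pct_hi intensity band in percent of heart-rate reserve,
#'   `0 < pct_lo < pct_hi <= 100`.
#' @return list of class `target_hr_zone` with integer `lo_bpm`, `hi_bpm`.
#' @export
target_hr_zone <- function(hrrest, hrmax, pct_lo, pct_hi) {
  fl_assert(hrrest < hrmax, "fitloop_validation_error",
            "hrrest (%.1f) must be below hrmax (%.1f)", hrrest, hrmax)
  fl_assert(pct_lo > 0 && pct_lo < pct_hi && pct_hi <= 100,
            "fitloop_validation_error",
            "need 0 < pct_lo < pct_hi <= 100")
  half_up <- function(x) floor(x + 0.5)
  lo <- half_up(hrrest + pct_lo / 100 * (hrmax - hrrest))
  hi <- half_up(hrrest + pct_hi / 100 * (hrmax - hrrest))
  structure(list(lo_bpm = as.integer(lo), hi_bpm = as.integer(hi)),
            class = "target_hr_zone")
}

#' Effective resting heart rate for a calendar week
#'
#' The zone-personalization input: the mean of the available daily
#' resting-HR values of the preceding calendar week. When that week has no
#' values, the most recent earlier week with values is used; when no
#' measurement was ever uploaded, the baseline value; and when no baseline
#' exists either, the configured fallback of 65 bpm.
#'
#' @param ledger named numeric vector, names are ISO dates and values daily
#'   resting HR in bpm (`NA` = missing day).
#' @param week calendar week (1-based) whose zones are being personalized.
#' @param profile a [participant_profile()].
#' @param config a [run_config()].
#' @return effective resting heart rate in bpm.
#' @export
weekly_effective_hrrest <- function(ledger, week, profile,
                                    config = run_config()) {
  fl_assert(week >= 1, "fitloop_validation_error", "week must be >= 1")
  if (length(ledger)) {
    dates <- as.Date(names(ledger))
    day_index <- as.integer(dates - profile$start_date) + 1L
    for (w in rev(seq_len(week - 1))) {
      in_w <- day_index >= (w - 1L) * 7L + 1L & day_index <= w * 7L
      vals <- ledger[in_w]
      vals <- vals[!is.na(vals)]
      if (length(vals)) return(mean(vals))
    }
  }
  if (!is.na(profile$baseline_hrrest)) return(profile$baseline_hrrest)
  config$default_hrrest
}

#' Weekly day-kind pattern
#'
#' Every plan week prescribes three mandatory sessions, evenly spaced so that
#' no more than two activity days are consecutive, plus an optional session
#' on the sixth day: mandatory, rest, mandatory, rest, mandatory, optional,
#' rest.
#'
#' @param plan_week plan week, 1--12 (the pattern is the same for all weeks).
#' @return character vector of 7 day kinds.
#' @export
schedule_week <- function(plan_week) {
  fl_assert(plan_week >= 1 && plan_week <= 12, "fitloop_validation_error",
            "plan_week must be in 1..12")
  c("mandatory", "rest", "mandatory", "rest", "mandatory", "optional", "rest")
}

#' Initialize the intervention state
#'
#' @param profile a [participant_profile()].
#' @param config a [run_config()].
#' @return object of class `intervention_state`: the participant's position
#'   in the closed loop (calendar day/week, plan week, effective resting HR,
#'   weekly ledgers and per-week advance/hold history).
#' @export
new_intervention_state <- function(profile, config = run_config()) {
  structure(list(
    profile = profile,
    calendar_day = 0L,
    calendar_week = 1L,
    plan_week = 1L,
    effective_hrrest = weekly_effective_hrrest(numeric(0), 1, profile, config),
    optional_downloaded = FALSE,
    weekly_completed_min = 0,
    hrrest_ledger = numeric(0),
    history = data.frame(
      calendar_week = integer(0), plan_week = integer(0),
      decision = character(0), recommended_min = numeric(0),
      completed_min = numeric(0), effective_hrrest = numeric(0),
      zone_lo = integer(0), zone_hi = integer(0),
      optional_downloaded = logical(0), stringsAsFactors = FALSE
    )
  ), class = "intervention_state")
}

#' @export
print.intervention_state <- function(x, ...) {
  cat(sprintf(
    "<intervention_state> %s: day %d (calendar week %d, plan week %d), effective HRrest %.1f bpm\n",
    x$profile$user_id, x$calendar_day, x$calendar_week, x$plan_week,
    x$effective_hrrest))
  invisible(x)
}

plan_row <- function(state, config) {
  config$framework[state$plan_week, ]
}

#' Generate the prescription for a calendar date
#'
#' The day kind comes from [schedule_week()]; the endurance duration and the
#' intensity band come from the current plan week's framework row, with the
#' target zone evaluated by [target_hr_zone()] at the week's effective
#' resting HR. Override: regardless of compliance, the plan is forced to
#' week 12 in calendar week 12 and the first activity session of that week
#' is the 12-minute exercise field test.
#'
#' @param state an `intervention_state` current through the day before
#'   `date`.
#' @param date calendar date inside the 12-calendar-week window.
#' @param config a [run_config()].
#' @return a `prescription_record`.
#' @export
next_prescription <- function(state, date, config = run_config()) {
  date <- as.Date(date)
  day_index <- as.integer(date - state$profile$start_date) + 1L
  n_weeks <- nrow(config$framework)
  fl_assert(day_index >= 1L && day_index <= n_weeks * 7L,
            "fitloop_window_error",
            "date %s is outside the %d-week intervention window",
            format(date), n_weeks)
  cal_week <- (day_index - 1L) %/% 7L + 1L
  dow <- (day_index - 1L) %% 7L + 1L
  plan_week <- if (cal_week == n_weeks) n_weeks else state$plan_week
  row <- config$framework[plan_week, ]
  kind <- schedule_week(plan_week)[dow]
  if (cal_week == n_weeks && dow == 1L) kind <- "eft"
  if (kind == "rest") {
    return(prescription_record(date, "rest", 0L, 0L, 0L, plan_week))
  }
  zone <- target_hr_zone(state$effective_hrrest, state$profile$hrmax,
                         row$pct_lo, row$pct_hi)
  endurance <- if (kind == "eft") config$eft_min else row$endurance_min
  prescription_record(date, kind, endurance, zone$lo_bpm, zone$hi_bpm,
                      plan_week)
}

#' Weekly compliance check
#'
#' Run at the end of each calendar week. Week 1 always advances (the check
#' starts at the end of week 2). For later weeks the plan advances when the
#' completed endurance minutes credited during the week reach at least 70%
#' of the recommended total; strictly less holds the plan at the same week.
#' The recommended total is three mandatory endurance durations, plus the
#' optional session's duration when its prescription file was downloaded
#' that week. Completed minutes only count files ingested before the week
#' rollover (late uploads are excluded upstream).
#'
#' @param state an `intervention_state` positioned at a week boundary.
#' @param config a [run_config()].
#' @return list with `decision` ("advance" or "hold"), `recommended_min`,
#'   `completed_min`.
#' @export
weekly_compliance_check <- function(state, config = run_config()) {
  row <- plan_row(state, config)
  recommended <- 3 * row$endurance_min +
    if (isTRUE(state$optional_downloaded)) row$endurance_min else 0
  completed <- state$weekly_completed_min
  decision <- if (state$calendar_week == 1L) {
    "advance"
  } else if (completed >= config$compliance_fraction * recommended - 1e-9) {
    "advance"
  } else {
    "hold"
  }
  list(decision = decision, recommended_min = recommended,
       completed_min = completed)
}

#' Advance the intervention state by one day
#'
#' Updates the daily ledgers with the day's ingested data, and at each 7-day
#' boundary runs [weekly_compliance_check()], records the week in the state
#' history, advances or holds the plan week, applies the calendar-week-12
#' override, recomputes the effective resting HR for the new week and resets
#' the weekly counters.
#'
#' @param state an `intervention_state`.
#' @param date the next calendar day (skipped or duplicated dates raise a
#'   sequencing error).
#' @param day_data list with optional fields `hrrest` (daily resting HR in
#'   bpm or `NA`), `endurance_min` (qualifying endurance minutes credited to
#'   the current week by today's ingest), `optional_downloaded` (logical).
#' @param config a [run_config()].
#' @return the updated `intervention_state`.
#' @export
advance_day <- function(state, date, day_data = list(),
                        config = run_config()) {
  date <- as.Date(date)
  expected <- state$profile$start_date + state$calendar_day
  fl_assert(date == expected, "fitloop_sequence_error",
            "expected day %s, got %s", format(expected), format(date))
  n_weeks <- nrow(config$framework)
  fl_assert(state$calendar_day < n_weeks * 7L, "fitloop_window_error",
            "intervention window already complete")
  state$calendar_day <- state$calendar_day + 1L
  state$calendar_week <- (state$calendar_day - 1L) %/% 7L + 1L
  hrrest <- day_data$hrrest %||% NA_real_
  state$hrrest_ledger[format(date)] <- hrrest
  state$weekly_completed_min <- state$weekly_completed_min +
    (day_data$endurance_min %||% 0)
  if (isTRUE(day_data$optional_downloaded)) state$optional_downloaded <- TRUE
  if (state$calendar_day %% 7L == 0L) {
    chk <- weekly_compliance_check(state, config)
    row <- plan_row(state, config)
    zone <- target_hr_zone(state$effective_hrrest, state$profile$hrmax,
                           row$pct_lo, row$pct_hi)
    state$history <- rbind(state$history, data.frame(
      calendar_week = state$calendar_week, plan_week = state$plan_week,
      decision = chk$decision, recommended_min = chk$recommended_min,
      completed_min = chk$completed_min,
      effective_hrrest = state$effective_hrrest,
      zone_lo = zone$lo_bpm, zone_hi = zone$hi_bpm,
      optional_downloaded = state$optional_downloaded,
      stringsAsFactors = FALSE
    ))
    if (state$calendar_day < n_weeks * 7L) {
      new_week <- state$calendar_week + 1L
      if (chk$decision == "advance") {
        state$plan_week <- min(state$plan_week + 1L, n_weeks)
      }
      if (new_week == n_weeks) state$plan_week <- n_weeks
      state$calendar_week <- new_week
      state$effective_hrrest <- weekly_effective_hrrest(
        state$hrrest_ledger, new_week, state$profile, config)
      state$weekly_completed_min <- 0
      state$optional_downloaded <- FALSE
    }
  }
  state
}
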