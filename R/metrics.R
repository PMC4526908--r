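# Training-impulse (TRIMP) dose quantification and the pluggable
# field-test fitness estimate.

#' Training impulse (TRIMP)
#'
#' `TRIMP = duration (min) * HRr * exp(k * HRr)` with the sex-specific
#' exponential scaling coefficient `k` (1.92 for men, 1.67 for women).
#' Captures both the duration and the relative heart-rate intensity of a
#' walking or running session in arbitrary units.
#'
#' @param duration_min exercise time in minutes (>= 0).
#' @param hrr heart-rate-reserve ratio, in `[0, 1.5]`.
#' @param sex "M" or "F".
#' @param config a [run_config()] (carries the coefficients).
#' @return TRIMP in arbitrary units.
#' @export
trimp <- function(duration_min, hrr, sex, config = run_config()) {
  fl_assert(all(duration_min >= 0), "fitloop_validation_error",
            "duration_min must be >= 0")
  fl_assert(all(hrr >= 0 & hrr <= 1.5), "fitloop_validation_error",
            "hrr must be in [0, 1.5]")
  fl_assert(all(sex %in% c("M", "F")), "fitloop_validation_error",
            "sex must be 'M' or 'F'")
  k <- config$trimp_k[sex]
  unname(duration_min * hrr * exp(k * hrr))
}

#' Recommended heart-rate-reserve ratio of an intensity band
#'
#' The midpoint of the prescribed %HRR band divided by 100; e.g. a 40--50
#' %HRR zone gives 0.45. Used for the recommended TRIMP.
#'
#' @param pct_lo,pct_hi intensity band in percent of heart-rate reserve.
#' @return ratio in (0, 1].
#' @export
recommended_hrr <- function(pct_lo, pct_hi) {
  fl_assert(all(pct_lo > 0 & pct_lo < pct_hi & pct_hi <= 100),
            "fitloop_validation_error", "need 0 < pct_lo < pct_hi <= 100")
  (pct_lo + pct_hi) / 200
}

#' Heart-rate-reserve ratio of a completed session
#'
#' Default mode `"reserve"` computes the fraction of heart-rate reserve
#' actually used, `(mean endurance HR - daily HRrest) / (HRmax - daily
#' HRrest)`, clipped to `[0, 1.5]` -- the reading commensurate with the
#' recommended ratio of [recommended_hrr()]. Mode `"literal"` divides the
#' endurance mean by the daily resting HR instead; it is preserved because
#' the system's original description admits that reading, but it is not
#' dimensionally comparable with the recommended ratio.
#'
#' @param mean_endurance_hr mean heart rate over the endurance phase, bpm.
#' @param hrrest_day that day's resting heart rate, bpm.
#' @param hrmax maximum heart rate, bpm (ignored in literal mode).
#' @param mode "reserve" (default) or "literal".
#' @return heart-rate-reserve ratio.
#' @export
completed_hrr <- function(mean_endurance_hr, hrrest_day, hrmax = NULL,
                          mode = c("reserve", "literal")) {
  mode <- match.arg(mode)
  fl_assert(all(mean_endurance_hr > 0), "fitloop_validation_error",
            "mean_endurance_hr must be positive")
  if (mode == "literal") return(mean_endurance_hr / hrrest_day)
  fl_assert(all(hrrest_day < hrmax), "fitloop_validation_error",
            "hrrest_day must be below hrmax")
  pmin(pmax((mean_endurance_hr - hrrest_day) / (hrmax - hrrest_day), 0), 1.5)
}

#' Weekly recommended and completed dose table
#'
#' One row per calendar week: recommended and completed endurance minutes
#' and TRIMP. Recommended TRIMP is `sessions * trimp(endurance_min,
#' recommended_hrr, sex)` with `sessions = 3` plus one when the optional
#' prescription was downloaded; completed TRIMP sums over the week's
#' qualifying sessions with each session's own endurance duration, mean
#' endurance HR and that day's resting HR.
#'
#' @param history the `history` data.frame of a completed
#'   `intervention_state` (one row per calendar week).
#' @param sessions data.frame of qualifying sessions with columns `date`,
#'   `endurance_min`, `mean_hr`, `excluded` (as built by the store).
#' @param profile a [participant_profile()].
#' @param ledger named daily resting-HR vector (see
#'   [weekly_effective_hrrest()]); a session day without a value falls back
#'   to the week's effective resting HR.
#' @param config a [run_config()].
#' @return data.frame with one row per week: `week`, `plan_week`,
#'   `recommended_min`, `completed_min`, `recommended_trimp`,
#'   `completed_trimp`, `decision`.
#' @export
weekly_dose <- function(history, sessions, profile, ledger = numeric(0),
                        config = run_config()) {
  out <- lapply(seq_len(nrow(history)), function(i) {
    h <- history[i, ]
    row <- config$framework[h$plan_week, ]
    n_sessions <- 3L + as.integer(isTRUE(h$optional_downloaded))
    rec_hrr <- recommended_hrr(row$pct_lo, row$pct_hi)
    rec_trimp <- n_sessions *
      trimp(row$endurance_min, rec_hrr, profile$sex, config)
    week_days <- profile$start_date + ((h$calendar_week - 1L) * 7L):(h$calendar_week * 7L - 1L)
    comp_trimp <- 0
    comp_min <- 0
    if (nrow(sessions)) {
      in_week <- as.Date(sessions$date) %in% week_days & !sessions$excluded
      for (j in which(in_week)) {
        s <- sessions[j, ]
        if (is.na(s$mean_hr) || s$endurance_min <= 0) next
        hrrest_day <- ledger[format(as.Date(s$date))]
        if (is.null(hrrest_day) || length(hrrest_day) == 0 || is.na(hrrest_day)) {
          hrrest_day <- h$effective_hrrest
        }
        hrr <- if (config$hrr_mode == "reserve") {
          completed_hrr(s$mean_hr, hrrest_day, profile$hrmax, "reserve")
        } else {
          completed_hrr(s$mean_hr, hrrest_day, mode = "literal")
        }
        comp_trimp <- comp_trimp +
          trimp(s$endurance_min, min(hrr, 1.5), profile$sex, config)
        comp_min <- comp_min + s$endurance_min
      }
    }
    data.frame(
      week = h$calendar_week, plan_week = h$plan_week,
      recommended_min = n_sessions * row$endurance_min,
      completed_min = comp_min,
      recommended_trimp = rec_trimp, completed_trimp = comp_trimp,
      decision = h$decision, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Estimate peak oxygen uptake from a field-test distance
#'
#' The 12-minute walk/run field test yields a distance from which
#' cardiorespiratory fitness can be estimated -- but only through an
#' externally supplied equation. No default equation ships with the package;
#' callers must register one via the `equation` argument.
#'
#' @param distance_m field-test distance in metres.
#' @param equation a function `f(distance_m) -> ml kg^-1 min^-1`.
#' @return estimated V-dot-O2peak.
#' @export
estimate_vo2peak <- function(distance_m, equation = NULL) {
  fl_assert(!is.null(equation) && is.function(equation),
            "fitloop_config_error",
            paste("no fitness-estimation equation registered; supply one as",
                  "`equation = function(distance_m) ...`"))
  equation(distance_m)
}

#' Export a weekly dose table
#'
#' Writes the table behind the recommended-vs-completed dose comparison as
#' both delimited text and JSON.
#'
#' @param dose data.frame from [weekly_dose()].
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @return `dose`, invisibly.
#' @export
export_weekly_dose <- function(dose, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(dose, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(dose, path_json, dataframe = "rows", digits = NA)
  }
  invisible(dose)
}
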