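# Signal filtering, quality-assurance rejection rules, resting-HR
# extraction, session phase segmentation and in-session zone feedback.

#' Trailing moving average
#'
#' Element `i` is the mean of elements `max(1, i - window + 1) .. i`
#' (trailing window, partial at the start of the series).
#'
#' @param x numeric vector.
#' @param window window length in elements (>= 1).
#' @return numeric vector the same length as `x`.
#' @export
trailing_moving_average <- function(x, window) {
  fl_assert(window >= 1, "fitloop_validation_error", "window must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - window + 1L, 1L)
  (cs - c(0, cs)[lo]) / (i - lo + 1L)
}

#' Extract beat values and times from a monitor file
#'
#' Beats are the rows where the heart-rate channel is nonzero (the dialect
#' records instantaneous HR only at beat-arrival rows).
#'
#' @param f an `am_file`.
#' @return data.frame with `t_offset` (s) and `hr` (bpm), one row per beat.
#' @export
extract_beats <- function(f) {
  s <- f$samples
  keep <- s$hr > 0L
  data.frame(t_offset = s$t_offset[keep], hr = as.numeric(s$hr[keep]))
}

#' Filter aberrant beats from a resting recording
#'
#' A beat is removed if it lies outside the absolute plausibility range
#' (default 30--220 bpm) or if it deviates from the trailing moving average
#' (default 10 beats) of the raw series by more than `filter_delta`
#' (default 25%) in relative terms. The moving-average reference and the
#' deviation threshold are configurable because the deviation criterion is a
#' design choice of this implementation.
#'
#' @param beats numeric vector of beat values in bpm.
#' @param config a [run_config()].
#' @return list with `clean` (retained beats), `fraction_filtered`
#'   (removed/total; 1 for an empty input), and `removed` (logical mask).
#' @export
filter_resting_beats <- function(beats, config = run_config()) {
  n <- length(beats)
  if (n == 0L) {
    return(list(clean = numeric(0), fraction_filtered = 1,
                removed = logical(0)))
  }
  ma <- trailing_moving_average(beats, config$ma_window)
  out_of_range <- beats < config$beat_range[1] | beats > config$beat_range[2]
  deviant <- abs(beats - ma) / ma > config$filter_delta
  removed <- out_of_range | deviant
  list(
    clean = beats[!removed],
    fraction_filtered = mean(removed),
    removed = removed
  )
}

qc_result <- function(accepted, reason, fraction_filtered = NA_real_,
                      mean_hr = NA_real_) {
  structure(list(
    accepted = accepted,
    reason = reason,
    fraction_filtered = fraction_filtered,
    mean_hr = mean_hr
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %s (%s)%s%s\n",
              if (x$accepted) "accepted" else "rejected", x$reason,
              if (!is.na(x$fraction_filtered))
                sprintf(", %.1f%% filtered", 100 * x$fraction_filtered) else "",
              if (!is.na(x$mean_hr))
                sprintf(", mean HR %.1f bpm", x$mean_hr) else ""))
  invisible(x)
}

#' Quality control of a resting heart-rate file
#'
#' A resting file is rejected when it is strictly shorter than 7.5 minutes
#' (`too_short`) or when strictly more than 20% of its beats are removed by
#' [filter_resting_beats()] (`over_filtered`). Boundary cases (exactly 7.5
#' minutes; exactly 20% filtered) are accepted, following the rule's strict
#' inequalities. A file with no beats at all is `over_filtered` with
#' `fraction_filtered = 1`; a zero-sample file is `empty`.
#'
#' @param f an `am_file` with `mode = "resting"`.
#' @param config a [run_config()].
#' @return a `qc_result`.
#' @export
resting_file_qc <- function(f, config = run_config()) {
  fl_assert(f$mode == "resting", "fitloop_mode_error",
            "resting_file_qc requires a resting file, got mode '%s'", f$mode)
  if (nrow(f$samples) == 0L) return(qc_result(FALSE, "empty"))
  if (duration_minutes(f) < config$min_resting_min) {
    return(qc_result(FALSE, "too_short"))
  }
  flt <- filter_resting_beats(extract_beats(f)$hr, config)
  mean_hr <- if (length(flt$clean)) mean(flt$clean) else NA_real_
  if (flt$fraction_filtered > config$max_fraction_filtered) {
    return(qc_result(FALSE, "over_filtered", flt$fraction_filtered, mean_hr))
  }
  qc_result(TRUE, "ok", flt$fraction_filtered, mean_hr)
}

#' Daily resting heart rate from an accepted resting file
#'
#' Mean of the clean (filtered) beats whose `t_offset` lies in the 5-minute
#' window centred at the file midpoint: minutes 2.5--7.5 of a 10-minute file,
#' minutes 1.5--6.5 of an 8-minute file, and so on. The window is half-open
#' (`t >= centre - 150` and `t < centre + 150` seconds).
#'
#' @param f an `am_file` that passed [resting_file_qc()].
#' @param config a [run_config()].
#' @return daily resting heart rate in bpm.
#' @export
daily_hrrest <- function(f, config = run_config()) {
  fl_assert(f$mode == "resting", "fitloop_mode_error",
            "daily_hrrest requires a resting file, got mode '%s'", f$mode)
  beats <- extract_beats(f)
  flt <- filter_resting_beats(beats$hr, config)
  t_clean <- beats$t_offset[!flt$removed]
  centre <- duration_minutes(f) * 60 / 2
  in_win <- t_clean >= centre - 150 & t_clean < centre + 150
  fl_assert(any(in_win), "fitloop_computation_error",
            "no clean beats in the middle 5-minute window")
  mean(flt$clean[in_win])
}

#' Quality control of an activity file
#'
#' An activity file is excluded from dose accounting when it contains no
#' heart-rate data at all (`no_hr`) or when the session-average heart rate
#' (over beat rows) is strictly below 80 bpm (`low_mean_hr`); a mean of
#' exactly 80 bpm is accepted.
#'
#' @param f an `am_file` with `mode = "activity"`.
#' @param config a [run_config()].
#' @return a `qc_result`.
#' @export
activity_file_qc <- function(f, config = run_config()) {
  fl_assert(f$mode == "activity", "fitloop_mode_error",
            "activity_file_qc requires an activity file, got mode '%s'", f$mode)
  if (nrow(f$samples) == 0L) return(qc_result(FALSE, "empty"))
  beats <- extract_beats(f)
  if (nrow(beats) == 0L) return(qc_result(FALSE, "no_hr"))
  mean_hr <- mean(beats$hr)
  if (mean_hr < config$min_activity_hr) {
    return(qc_result(FALSE, "low_mean_hr", mean_hr = mean_hr))
  }
  qc_result(TRUE, "ok", mean_hr = mean_hr)
}

#' Segment an activity session into phases and summarize it
#'
#' Phases are assigned by recorded time: the first 5 minutes are warm-up,
#' the last 5 minutes cool-down, and the remainder endurance. Files of 10
#' recorded minutes or less have no endurance phase. The endurance mean heart
#' rate is computed over endurance beat rows only.
#'
#' @param f an `am_file` accepted by [activity_file_qc()].
#' @param p the day's `prescription_record` (used for provenance; phase
#'   boundaries come from recorded time and the configured phase durations).
#' @param config a [run_config()].
#' @return list of class `session_summary` with `day`, `total_min`,
#'   `endurance_min`, `endurance_mean_hr` (NA when there is no endurance
#'   phase or no endurance beats).
#' @export
segment_and_summarize <- function(f, p = NULL, config = run_config()) {
  total_min <- duration_minutes(f)
  w <- config$warmup_min
  cd <- config$cooldown_min
  endurance_min <- max(total_min - w - cd, 0)
  mean_hr <- NA_real_
  if (endurance_min > 0) {
    beats <- extract_beats(f)
    in_end <- beats$t_offset >= w * 60 &
      beats$t_offset < (total_min - cd) * 60
    if (any(in_end)) mean_hr <- mean(beats$hr[in_end])
  }
  structure(list(
    day = f$file_date,
    total_min = total_min,
    endurance_min = endurance_min,
    endurance_mean_hr = mean_hr
  ), class = "session_summary")
}

#' In-session feedback events
#'
#' Reproduces the monitor's light feedback as an event stream: a phase-end
#' event at the end of warm-up, endurance and cool-down (at minutes
#' `warmup`, `warmup + endurance`, `warmup + endurance + cooldown` of the
#' prescription), and, during the endurance phase only, an `above_zone` /
#' `below_zone` event each time the trailing 5-beat moving average of
#' instantaneous heart rate crosses out of the target zone (one event per
#' entry into violation, not one per beat).
#'
#' @param f the session's `am_file`.
#' @param p the day's `prescription_record` (`kind != "rest"`).
#' @param config a [run_config()].
#' @return data.frame with `t_offset` (seconds) and `kind`.
#' @export
feedback_events <- function(f, p, config = run_config()) {
  fl_assert(p$kind != "rest", "fitloop_validation_error",
            "no feedback on a rest day")
  t1 <- p$warmup_min * 60
  t2 <- (p$warmup_min + p$endurance_min) * 60
  t3 <- (p$warmup_min + p$endurance_min + p$cooldown_min) * 60
  events <- data.frame(
    t_offset = c(t1, t2, t3),
    kind = c("phase_end_warmup", "phase_end_endurance", "phase_end_cooldown"),
    stringsAsFactors = FALSE
  )
  beats <- extract_beats(f)
  if (nrow(beats)) {
    ma <- trailing_moving_average(beats$hr, config$feedback_ma_beats)
    in_end <- beats$t_offset >= t1 & beats$t_offset < t2
    t_end <- beats$t_offset[in_end]
    ma_end <- ma[in_end]
    state <- "in"
    zt <- numeric(0)
    zk <- character(0)
    for (i in seq_along(ma_end)) {
      new_state <- if (ma_end[i] > p$zone_hi_bpm) "above"
        else if (ma_end[i] < p$zone_lo_bpm) "below" else "in"
      if (new_state != state && new_state != "in") {
        zt <- c(zt, t_end[i])
        zk <- c(zk, paste0(new_state, "_zone"))
      }
      state <- new_state
    }
    if (length(zt)) {
      events <- rbind(events, data.frame(t_offset = zt, kind = zk,
                                         stringsAsFactors = FALSE))
    }
  }
  events[order(events$t_offset, match(events$kind, unique(events$kind))), ,
         drop = FALSE]
}
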