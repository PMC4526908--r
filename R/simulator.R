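# Synthetic participants: physiology, compliance behaviour and monitor-file
# generation, plus the driver that runs the full closed loop without a
# device or human subjects.

#' Construct a synthetic physiology profile
#'
#' @param hrrest0 resting heart rate at day 0, bpm.
#' @param hrmax maximum heart rate, bpm.
#' @param hrrest_drift resting-HR change in bpm per week (negative models a
#'   training adaptation).
#' @param zone_bias fraction of the target-zone width by which endurance HR
#'   deviates from the zone midpoint (0 = trains exactly at the midpoint,
#'   +1 = a full zone-width above it).
#' @param hr_noise_sd beat-to-beat (and day-to-day) heart-rate noise, bpm.
#' @param aberrant_rate probability per beat of an artifact beat (spike in
#'   120--200 bpm or drop to 30--45 bpm), in `[0, 0.5]`.
#' @return object of class `physiology_profile`.
#' @export
physiology_profile <- function(hrrest0, hrmax, hrrest_drift = 0,
                               zone_bias = 0, hr_noise_sd = 2,
                               aberrant_rate = 0) {
  fl_assert(hrrest0 < hrmax, "fitloop_validation_error",
            "hrrest0 must be below hrmax")
  fl_assert(aberrant_rate >= 0 && aberrant_rate <= 0.5,
            "fitloop_validation_error", "aberrant_rate must be in [0, 0.5]")
  structure(list(
    hrrest0 = hrrest0, hrmax = hrmax, hrrest_drift = hrrest_drift,
    zone_bias = zone_bias, hr_noise_sd = hr_noise_sd,
    aberrant_rate = aberrant_rate
  ), class = "physiology_profile")
}

#' Construct a synthetic compliance profile
#'
#' @param p_mandatory per-session completion probability for mandatory
#'   sessions (and the field test).
#' @param p_optional probability the optional day's prescription is
#'   downloaded (a downloaded optional session is then completed with
#'   `p_mandatory`).
#' @param p_resting per-day probability of performing the resting
#'   measurement.
#' @param upload_lag_probs named numeric vector of probabilities over lag
#'   days (names "0", "1", ...); uploads happen `lag` days after recording.
#' @param blackout_windows list of `c(from_day, to_day)` day-index ranges
#'   during which no uploads or downloads happen (no computer access); files
#'   whose upload falls in a window are lost.
#' @param p_mandatory_late optional completion probability that replaces
#'   `p_mandatory` from `late_from_week` onwards (models waning adherence).
#' @param late_from_week calendar week at which `p_mandatory_late` starts.
#' @return object of class `compliance_profile`.
#' @export
compliance_profile <- function(p_mandatory = 1, p_optional = 0,
                               p_resting = 1,
                               upload_lag_probs = c("0" = 1),
                               blackout_windows = list(),
                               p_mandatory_late = NULL,
                               late_from_week = NULL) {
  probs <- c(p_mandatory, p_optional, p_resting, p_mandatory_late)
  fl_assert(all(probs >= 0 & probs <= 1), "fitloop_validation_error",
            "probabilities must be in [0, 1]")
  fl_assert(abs(sum(upload_lag_probs) - 1) < 1e-9, "fitloop_validation_error",
            "upload_lag_probs must sum to 1")
  structure(list(
    p_mandatory = p_mandatory, p_optional = p_optional,
    p_resting = p_resting, upload_lag_probs = upload_lag_probs,
    blackout_windows = blackout_windows,
    p_mandatory_late = p_mandatory_late, late_from_week = late_from_week
  ), class = "compliance_profile")
}

#' Preset synthetic participants
#'
#' Two documented parameter sets: `"adherent"` (completes everything, daily
#' resting uploads, no lag, slow training-adaptation decline in resting HR)
#' and `"sporadic"` (full adherence for three weeks, then 35% session
#' completion, occasional one-day upload lag, and a no-computer-access
#' blackout over weeks 9--12).
#'
#' @param name "adherent" or "sporadic".
#' @return list with elements `phys` and `compliance`.
#' @export
preset_profiles <- function(name) {
  fl_assert(is.character(name) && length(name) == 1L,
            "fitloop_config_error", "preset name must be a single string")
  switch(name,
    adherent = list(
      phys = physiology_profile(hrrest0 = 65, hrmax = 190,
                                hrrest_drift = -0.3, zone_bias = 0,
                                hr_noise_sd = 2, aberrant_rate = 0.01),
      compliance = compliance_profile(p_mandatory = 1, p_optional = 1,
                                      p_resting = 1)
    ),
    sporadic = list(
      phys = physiology_profile(hrrest0 = 68, hrmax = 185,
                                hrrest_drift = -0.1, zone_bias = -0.2,
                                hr_noise_sd = 3, aberrant_rate = 0.05),
      compliance = compliance_profile(
        p_mandatory = 1, p_optional = 0.2, p_resting = 0.8,
        upload_lag_probs = c("0" = 0.7, "1" = 0.3),
        blackout_windows = list(c(57L, 84L)),
        p_mandatory_late = 0.35, late_from_week = 4L
      )
    ),
    fl_stop("fitloop_config_error", "unknown preset '%s'", name)
  )
}

# True (noise-free apart from the daily term) resting HR on a given day.
true_daily_hrrest <- function(phys, day_index, day_noise = 0) {
  phys$hrrest0 + phys$hrrest_drift * day_index / 7 + day_noise
}

# Beat arrival times (seconds) for a per-second heart-rate trajectory (bpm).
beat_times_from_traj <- function(traj) {
  cb <- cumsum(traj / 60)
  nb <- floor(cb[length(cb)])
  if (nb < 1) return(numeric(0))
  stats::approx(x = c(0, cb), y = 0:length(cb), xout = seq_len(nb))$y
}

# Assemble an am_file from beat times/values over a duration.
build_am_samples <- function(beat_t, beat_hr, duration_s, sample_rate,
                             gait = FALSE) {
  n <- as.integer(round(duration_s * sample_rate))
  hr <- integer(n)
  row <- pmin(floor(beat_t * sample_rate) + 1L, n)
  hr[row] <- as.integer(round(pmin(pmax(beat_hr, 20), 250)))
  if (gait) {
    ax <- rnorm(n, 0, 0.4)
    ay <- rnorm(n, 0, 0.4)
    az <- 1 + 0.8 * sin(2 * pi * 1.8 * seq_len(n) / sample_rate) +
      rnorm(n, 0, 0.2)
  } else {
    ax <- rnorm(n, 0, 0.03)
    ay <- 1 + rnorm(n, 0, 0.03)
    az <- rnorm(n, 0, 0.03)
  }
  clamp <- function(v) pmin(pmax(v, -8), 8)
  data.frame(
    t_offset = (seq_len(n) - 1L) / sample_rate,
    ax = clamp(ax), ay = clamp(ay), az = clamp(az), hr = hr
  )
}

inject_artifacts <- function(beat_hr, rate) {
  if (rate <= 0 || !length(beat_hr)) return(beat_hr)
  hit <- runif(length(beat_hr)) < rate
  if (!any(hit)) return(beat_hr)
  n_hit <- sum(hit)
  spike <- runif(n_hit) < 0.5
  beat_hr[hit] <- ifelse(spike, runif(n_hit, 120, 200), runif(n_hit, 30, 45))
  beat_hr
}

#' Simulate a supine resting heart-rate recording
#'
#' Emulates a 10-minute morning resting measurement: the true daily resting
#' HR is `hrrest0 + hrrest_drift * day_index / 7` plus a day-level noise term
#' (sd = `hr_noise_sd`); individual beats scatter around it with the same sd,
#' and artifact beats are injected at `aberrant_rate`.
#'
#' @param phys a [physiology_profile()].
#' @param day_index 1-based intervention day.
#' @param seed optional seed (see [with_seed()]); `NULL` uses the ambient
#'   RNG stream.
#' @param user_id,date,time file identity fields.
#' @param minutes recording length (default 10).
#' @param config a [run_config()].
#' @return an `am_file` with `mode = "resting"`.
#' @export
simulate_resting_file <- function(phys, day_index, seed = NULL,
                                  user_id = "sim", date = NULL,
                                  time = "07:00:00", minutes = 10,
                                  config = run_config()) {
  date <- date %||% (as.Date("2020-01-06") + day_index - 1L)
  with_seed(seed, {
    true_hr <- true_daily_hrrest(phys, day_index,
                                 rnorm(1, 0, phys$hr_noise_sd))
    true_hr <- max(true_hr, 35)
    dur_s <- minutes * 60
    traj <- rep(true_hr, ceiling(dur_s))
    beat_t <- beat_times_from_traj(traj)
    beat_t <- beat_t[beat_t < dur_s]
    beat_hr <- true_hr + rnorm(length(beat_t), 0, phys$hr_noise_sd)
    beat_hr <- inject_artifacts(beat_hr, phys$aberrant_rate)
    samples <- build_am_samples(beat_t, beat_hr, dur_s, config$sample_rate)
    am_file(user_id, date, time, "resting", samples, config$sample_rate)
  })
}

#' Simulate an activity-session recording against a prescription
#'
#' The session lasts exactly `warmup + endurance + cooldown` minutes. Heart
#' rate ramps linearly from the day's resting value to the endurance target
#' during warm-up; during endurance it follows a first-order autocorrelated
#' process (coefficient 0.9) around `zone midpoint + zone_bias * zone width`;
#' during cool-down it decays exponentially back toward rest. Accelerations
#' are cosmetic gait-like magnitudes -- quality control never reads them.
#'
#' @param phys a [physiology_profile()].
#' @param p the day's `prescription_record` (`kind != "rest"`).
#' @param hrrest_day that day's resting HR, bpm (default: profile baseline).
#' @param seed optional seed; `NULL` uses the ambient stream.
#' @param user_id,time file identity fields (the date comes from `p$date`).
#' @param ar_coef autocorrelation coefficient of the endurance HR process.
#' @param config a [run_config()].
#' @return an `am_file` with `mode = "activity"`.
#' @export
simulate_activity_file <- function(phys, p, hrrest_day = phys$hrrest0,
                                   seed = NULL, user_id = "sim",
                                   time = "18:00:00", ar_coef = 0.9,
                                   config = run_config()) {
  fl_assert(p$kind != "rest", "fitloop_validation_error",
            "cannot simulate a session for a rest day")
  with_seed(seed, {
    w_s <- p$warmup_min * 60
    e_s <- p$endurance_min * 60
    c_s <- p$cooldown_min * 60
    mid <- (p$zone_lo_bpm + p$zone_hi_bpm) / 2
    width <- p$zone_hi_bpm - p$zone_lo_bpm
    target <- mid + phys$zone_bias * width
    warm <- seq(hrrest_day, target, length.out = w_s)
    innov_sd <- phys$hr_noise_sd * sqrt(1 - ar_coef^2)
    x <- numeric(e_s)
    if (e_s > 0) {
      x[1] <- rnorm(1, 0, phys$hr_noise_sd)
      for (s in seq_len(e_s - 1L)) {
        x[s + 1L] <- ar_coef * x[s] + rnorm(1, 0, innov_sd)
      }
    }
    endur <- target + x
    last <- if (e_s > 0) endur[e_s] else target
    cool <- hrrest_day + 10 + (last - hrrest_day - 10) * exp(-seq_len(c_s) / 90)
    traj <- pmax(c(warm, endur, cool), 35)
    dur_s <- w_s + e_s + c_s
    beat_t <- beat_times_from_traj(traj)
    beat_t <- beat_t[beat_t < dur_s]
    beat_hr <- stats::approx(x = seq_along(traj), y = traj,
                             xout = pmax(beat_t, 1), rule = 2)$y
    samples <- build_am_samples(beat_t, beat_hr, dur_s, config$sample_rate,
                                gait = TRUE)
    am_file(user_id, p$date, time, "activity", samples, config$sample_rate)
  })
}

in_blackout <- function(compliance, day_index) {
  for (w in compliance$blackout_windows) {
    if (day_index >= w[1] && day_index <= w[2]) return(TRUE)
  }
  FALSE
}

draw_lag <- function(compliance) {
  lags <- as.integer(names(compliance$upload_lag_probs))
  if (length(lags) == 1L) return(lags)
  sample(lags, 1L, prob = compliance$upload_lag_probs)
}

p_session <- function(compliance, cal_week) {
  if (!is.null(compliance$late_from_week) &&
      cal_week >= compliance$late_from_week) {
    compliance$p_mandatory_late
  } else {
    compliance$p_mandatory
  }
}

#' Run the full closed loop with a synthetic participant
#'
#' Day-by-day driver: the engine prescribes, the synthetic participant
#' stochastically downloads, completes and uploads per the compliance
#' profile, files are ingested and quality-controlled, triggers are scanned
#' and the intervention state advances. Fully deterministic given `seed`.
#'
#' @param phys a [physiology_profile()].
#' @param compliance a [compliance_profile()].
#' @param profile optional [participant_profile()]; derived from `phys` when
#'   `NULL` (male, baseline = `hrrest0`, start 2020-01-06).
#' @param weeks number of intervention weeks (default the framework length).
#' @param seed integer seed for all randomness.
#' @param config a [run_config()].
#' @return list with `store` (a `pa_store` including the event log),
#'   `state` (final `intervention_state`), `history` (per-week engine
#'   decisions), `dose` (the [weekly_dose()] table) and `prescriptions`
#'   (list of every daily `prescription_record`).
#' @export
run_closed_loop <- function(phys, compliance, profile = NULL, weeks = NULL,
                            seed = 1L, config = run_config()) {
  weeks <- weeks %||% nrow(config$framework)
  fl_assert(weeks == nrow(config$framework), "fitloop_config_error",
            "weeks (%d) must match the framework length (%d); supply a shorter framework to shorten the run",
            weeks, nrow(config$framework))
  profile <- profile %||% participant_profile(
    user_id = "sim", sex = "M", baseline_hrrest = round(phys$hrrest0),
    hrmax = phys$hrmax, start_date = as.Date("2020-01-06"))
  with_seed(seed, {
    state <- new_intervention_state(profile, config)
    store <- new_store(profile, config)
    store <- append_events(store, milestone_emails(profile, config))
    pending <- vector("list", weeks * 7L + 1L)
    prescriptions <- vector("list", weeks * 7L)
    for (d in seq_len(weeks * 7L)) {
      date <- profile$start_date + d - 1L
      cal_week <- (d - 1L) %/% 7L + 1L
      blackout <- in_blackout(compliance, d)
      p <- next_prescription(state, date, config)
      prescriptions[[d]] <- p
      downloaded <- !blackout &&
        (p$kind != "optional" || runif(1) < compliance$p_optional)
      store <- mark_prescription_downloaded(store, date, downloaded)
      new_files <- list()
      if (runif(1) < compliance$p_resting) {
        new_files <- c(new_files, list(simulate_resting_file(
          phys, d, user_id = profile$user_id, date = date, config = config)))
      }
      if (p$kind != "rest" && downloaded &&
          runif(1) < p_session(compliance, cal_week)) {
        hrrest_day <- true_daily_hrrest(phys, d)
        new_files <- c(new_files, list(simulate_activity_file(
          phys, p, hrrest_day = hrrest_day, user_id = profile$user_id,
          config = config)))
      }
      for (f in new_files) {
        due <- d + draw_lag(compliance)
        while (due <= weeks * 7L && in_blackout(compliance, due)) {
          due <- due + 1L
        }
        if (due <= weeks * 7L && !in_blackout(compliance, due)) {
          pending[[due]] <- c(pending[[due]], list(f))
        }
      }
      n_sessions_before <- nrow(store$sessions)
      if (length(pending[[d]])) {
        store <- ingest_uploads(store, pending[[d]], date)
      }
      store <- append_events(store, scan_triggers(store, date))
      new_sessions <- store$sessions[
        seq_len(nrow(store$sessions)) > n_sessions_before, , drop = FALSE]
      week_start <- profile$start_date + (cal_week - 1L) * 7L
      credited <- if (nrow(new_sessions)) {
        keep <- !new_sessions$excluded & new_sessions$date >= week_start
        sum(new_sessions$endurance_min[keep])
      } else 0
      state <- advance_day(state, date, list(
        hrrest = store$days$resting_value[day_row(store, date)],
        endurance_min = credited,
        optional_downloaded = p$kind == "optional" && downloaded
      ), config)
    }
    dose <- weekly_dose(state$history, store$sessions, profile,
                        state$hrrest_ledger, config)
    list(store = store, state = state, history = state$history,
         dose = dose, prescriptions = prescriptions)
  })
}
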