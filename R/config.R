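# Run configuration: every named constant of the intervention in one place.

#' The standard twelve-week intervention framework
#'
#' Returns the default progression table: one row per plan week with the
#' recommended session count, the target-intensity band in percent of
#' heart-rate reserve (%HRR), and the endurance duration in minutes
#' (exclusive of the fixed 5-minute warm-up and cool-down). Duration and
#' intensity increase in an alternating biweekly pattern (about +20% duration,
#' +5 %HRR). The table ships as a human-editable TSV so other populations can
#' re-parameterize it; see [read_framework()].
#'
#' @return data.frame with columns `week`, `sessions_min`, `sessions_max`,
#'   `pct_lo`, `pct_hi`, `endurance_min`.
#' @export
default_framework <- function() {
  path <- system.file("extdata", "framework.tsv", package = "fitloop")
  fl_assert(nzchar(path), "fitloop_config_error",
            "bundled framework table not found")
  read_framework(path)
}

#' Read an intervention framework table
#'
#' @param path tab-separated file with header
#'   `week sessions_min sessions_max pct_lo pct_hi endurance_min`.
#' @return validated framework data.frame (see [default_framework()]).
#' @export
read_framework <- function(path) {
  fw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_framework(fw)
  fw
}

validate_framework <- function(fw) {
  need <- c("week", "sessions_min", "sessions_max", "pct_lo", "pct_hi",
            "endurance_min")
  fl_assert(all(need %in% names(fw)), "fitloop_config_error",
            "framework table must have columns: %s", paste(need, collapse = ", "))
  fl_assert(identical(as.integer(fw$week), seq_len(nrow(fw))),
            "fitloop_config_error", "framework weeks must be 1..%d", nrow(fw))
  fl_assert(all(fw$pct_lo < fw$pct_hi), "fitloop_config_error",
            "framework pct_lo must be < pct_hi")
  fl_assert(all(fw$endurance_min > 0), "fitloop_config_error",
            "framework endurance_min must be positive")
  invisible(fw)
}

#' Configuration for the closed loop
#'
#' Collects every tunable threshold of the pipeline with the intervention's
#' default values: the resting-beat filter (10-beat trailing moving average,
#' relative deviation delta = 0.25, absolute beat range 30--220 bpm), the
#' resting-file acceptance rules (at least 7.5 minutes, at most 20% of beats
#' filtered), the activity-file acceptance rule (session mean heart rate at
#' least 80 bpm), the weekly compliance fraction (0.70), the fallback resting
#' heart rate used when no measurement exists (65 bpm), TRIMP scaling
#' coefficients (1.92 male, 1.67 female), and the monitor-file dialect's
#' sample rate (10 rows/s).
#'
#' @param framework intervention framework table ([default_framework()]).
#' @param ma_window trailing moving-average window (beats) for resting-beat
#'   filtering.
#' @param filter_delta maximum relative deviation of a beat from its trailing
#'   moving average before it is removed.
#' @param beat_range absolute plausibility bounds (bpm) for a beat.
#' @param min_resting_min minimum accepted resting-file length, minutes;
#'   files strictly shorter are rejected.
#' @param max_fraction_filtered maximum tolerated filtered-beat fraction;
#'   strictly greater rejects.
#' @param min_activity_hr minimum session-average heart rate (bpm) for an
#'   activity file to enter dose accounting; strictly lower rejects.
#' @param compliance_fraction weekly completed/recommended duration ratio at
#'   or above which the plan advances.
#' @param default_hrrest fallback resting heart rate (bpm) when neither a
#'   measurement nor a baseline exists.
#' @param warmup_min,cooldown_min fixed phase durations, minutes.
#' @param eft_min duration of the week-12 exercise field test, minutes.
#' @param trimp_k named numeric, TRIMP exponential coefficients for sexes
#'   `M` and `F`.
#' @param hrr_mode how completed-session heart-rate-reserve ratio is
#'   computed; see [completed_hrr()].
#' @param reminder_days consecutive days of missing resting data that trigger
#'   a reminder.
#' @param survey_days consecutive upload-free days that trigger a survey.
#' @param no_download_days consecutive days without a prescription download
#'   that trigger an administrator notification.
#' @param feedback_ma_beats moving-average window (beats) for in-session
#'   zone feedback.
#' @param sample_rate monitor-file rows per second (dialect constant).
#' @param seed optional integer seed recorded in the config; all simulator
#'   randomness flows from it.
#' @param store_dir optional default store directory for the CLI.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(framework = default_framework(),
                       ma_window = 10L,
                       filter_delta = 0.25,
                       beat_range = c(30, 220),
                       min_resting_min = 7.5,
                       max_fraction_filtered = 0.20,
                       min_activity_hr = 80,
                       compliance_fraction = 0.70,
                       default_hrrest = 65,
                       warmup_min = 5L,
                       cooldown_min = 5L,
                       eft_min = 12L,
                       trimp_k = c(M = 1.92, F = 1.67),
                       hrr_mode = c("reserve", "literal"),
                       reminder_days = 3L,
                       survey_days = 7L,
                       no_download_days = 3L,
                       feedback_ma_beats = 5L,
                       sample_rate = 10L,
                       seed = NULL,
                       store_dir = NULL) {
  hrr_mode <- match.arg(hrr_mode)
  validate_framework(framework)
  fl_assert(ma_window >= 1, "fitloop_config_error", "ma_window must be >= 1")
  fl_assert(filter_delta > 0, "fitloop_config_error", "filter_delta must be > 0")
  fl_assert(length(beat_range) == 2 && beat_range[1] < beat_range[2],
            "fitloop_config_error", "beat_range must be c(lo, hi) with lo < hi")
  fl_assert(compliance_fraction > 0 && compliance_fraction <= 1,
            "fitloop_config_error", "compliance_fraction must be in (0, 1]")
  fl_assert(all(c("M", "F") %in% names(trimp_k)), "fitloop_config_error",
            "trimp_k must name coefficients M and F")
  structure(list(
    framework = framework,
    ma_window = as.integer(ma_window),
    filter_delta = filter_delta,
    beat_range = as.numeric(beat_range),
    min_resting_min = min_resting_min,
    max_fraction_filtered = max_fraction_filtered,
    min_activity_hr = min_activity_hr,
    compliance_fraction = compliance_fraction,
    default_hrrest = default_hrrest,
    warmup_min = as.integer(warmup_min),
    cooldown_min = as.integer(cooldown_min),
    eft_min = as.integer(eft_min),
    trimp_k = trimp_k,
    hrr_mode = hrr_mode,
    reminder_days = as.integer(reminder_days),
    survey_days = as.integer(survey_days),
    no_download_days = as.integer(no_download_days),
    feedback_ma_beats = as.integer(feedback_ma_beats),
    sample_rate = as.integer(sample_rate),
    seed = seed,
    store_dir = store_dir
  ), class = "run_config")
}
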