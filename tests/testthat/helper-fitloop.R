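# Fixture builders: files are constructed in code, never stored on disk.

# A resting file whose beats arrive at a fixed 1-second cadence with the
# given bpm values (recycled to one beat per second over `minutes`).
make_resting_file <- function(beat_values, minutes = 10, user_id = "u01",
                              date = "2015-03-02", time = "07:15:00",
                              sample_rate = 10L) {
  n_beats <- minutes * 60
  vals <- rep_len(beat_values, n_beats)
  n <- as.integer(minutes * 60 * sample_rate)
  hr <- integer(n)
  hr[(0:(n_beats - 1)) * sample_rate + 1L] <- as.integer(round(vals))
  am_file(user_id, date, time, "resting",
          data.frame(t_offset = (seq_len(n) - 1L) / sample_rate,
                     ax = 0, ay = 1, az = 0, hr = hr),
          sample_rate = sample_rate)
}

# An activity file with one beat per second at the given bpm values.
make_activity_file <- function(beat_values, minutes = 30, user_id = "u01",
                               date = "2015-03-02", time = "18:30:00",
                               sample_rate = 10L) {
  n_beats <- minutes * 60
  vals <- rep_len(beat_values, n_beats)
  n <- as.integer(minutes * 60 * sample_rate)
  hr <- integer(n)
  hr[(0:(n_beats - 1)) * sample_rate + 1L] <- as.integer(round(vals))
  am_file(user_id, date, time, "activity",
          data.frame(t_offset = (seq_len(n) - 1L) / sample_rate,
                     ax = 0.2, ay = 0.1, az = 1, hr = hr),
          sample_rate = sample_rate)
}

# A random but valid small am_file, for round-trip property tests.
random_am_file <- function(n = 50L, mode = "activity") {
  samples <- data.frame(
    t_offset = cumsum(sample(1:5, n, replace = TRUE)) / 10,
    ax = round(runif(n, -8, 8), 3),
    ay = round(runif(n, -8, 8), 3),
    az = round(runif(n, -8, 8), 3),
    hr = sample(c(0L, 20:250), n, replace = TRUE)
  )
  am_file(
    user_id = paste(sample(c(letters, 0:9), sample(1:8, 1), replace = TRUE),
                    collapse = ""),
    file_date = as.Date("2015-01-01") + sample(0:364, 1),
    file_time = sprintf("%02d:%02d:%02d", sample(0:23, 1), sample(0:59, 1),
                        sample(0:59, 1)),
    mode = mode,
    samples = samples,
    sample_rate = 10L
  )
}

test_profile <- function(baseline = 65, hrmax = 190,
                         start = as.Date("2020-01-06")) {
  participant_profile("u01", "M", baseline, hrmax, start)
}

# Drive the engine for `weeks` full weeks with a fixed per-week completion
# fraction (of the 3-mandatory recommendation, optional never downloaded).
# Returns the final state.
drive_engine <- function(fraction_by_week, profile = test_profile(),
                         config = run_config()) {
  state <- new_intervention_state(profile, config)
  for (w in seq_along(fraction_by_week)) {
    row <- config$framework[state$plan_week, ]
    total <- fraction_by_week[w] * 3 * row$endurance_min
    for (dow in 1:7) {
      d <- profile$start_date + (w - 1L) * 7L + dow - 1L
      state <- advance_day(state, d, list(
        hrrest = NA_real_,
        endurance_min = if (dow == 1L) total else 0
      ), config)
    }
  }
  state
}
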