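# Naive reference implementations (oracles), kept deliberately independent
# of the package's vectorized code paths.
naive_trailing_ma <- function(x, w) {
  vapply(seq_along(x),
         function(i) mean(x[max(1, i - w + 1):i]), numeric(1))
}

naive_filter <- function(beats, config = run_config()) {
  ma <- naive_trailing_ma(beats, config$ma_window)
  removed <- beats < config$beat_range[1] | beats > config$beat_range[2] |
    abs(beats - ma) / ma > config$filter_delta
  list(clean = beats[!removed], fraction_filtered = mean(removed))
}

test_that("trailing moving average matches the hand and brute-force oracles", {
  expect_equal(trailing_moving_average(c(60, 60, 60, 60), 2),
               c(60, 60, 60, 60))
  expect_equal(trailing_moving_average(c(60, 70), 2), c(60, 65))
  expect_equal(trailing_moving_average(42, 10), 42)
  expect_identical(trailing_moving_average(numeric(0), 5), numeric(0))

  withr::local_seed(1)
  for (i in 1:10) {
    x <- runif(sample(1:60, 1), 40, 200)
    w <- sample(1:12, 1)
    expect_equal(trailing_moving_average(x, w), naive_trailing_ma(x, w))
  }
})

test_that("resting-beat filtering applies the range and deviation rules", {
  clean <- filter_resting_beats(rep(62, 600))
  expect_equal(clean$fraction_filtered, 0)
  expect_identical(clean$clean, rep(62, 600))

  beats <- rep(62, 100)
  beats[50] <- 180
  flt <- filter_resting_beats(beats)
  expect_equal(flt$fraction_filtered, 1 / 100)
  expect_false(180 %in% flt$clean)
  expect_equal(flt, c(naive_filter(beats), list(removed = flt$removed)),
               ignore_attr = TRUE)

  all_low <- filter_resting_beats(rep(10, 50))
  expect_equal(all_low$fraction_filtered, 1)
  expect_identical(all_low$clean, numeric(0))

  none <- filter_resting_beats(numeric(0))
  expect_equal(none$fraction_filtered, 1)
})

test_that("filtering is idempotent and matches the oracle on noisy signals", {
  withr::local_seed(7)
  for (i in 1:8) {
    beats <- 62 + rnorm(400, 0, 3)
    # artifacts away from the first partial windows: while the moving average
    # is still warming up, an artifact is its own reference and single-pass
    # filtering is not idempotent there (see the methods vignette)
    spikes <- c(rep(FALSE, 10), runif(390) < 0.05)
    beats[spikes] <- runif(sum(spikes), 120, 200)
    flt <- filter_resting_beats(beats)
    oracle <- naive_filter(beats)
    expect_equal(flt$clean, oracle$clean)
    expect_equal(flt$fraction_filtered, oracle$fraction_filtered)
    again <- filter_resting_beats(flt$clean)
    expect_identical(again$clean, flt$clean)
    expect_equal(again$fraction_filtered, 0)
    expect_true(flt$fraction_filtered >= 0 && flt$fraction_filtered <= 1)
  }
})

test_that("resting-file QC enforces the length and filtering boundaries", {
  expect_true(resting_file_qc(make_resting_file(62, minutes = 7.5))$accepted)
  expect_equal(resting_file_qc(make_resting_file(62, minutes = 6))$reason,
               "too_short")

  # exactly 20% filtered is accepted; just above is rejected
  beats20 <- rep(62, 600)
  beats20[seq(5, 600, 5)] <- 25          # 120/600 = 20% out of range
  f20 <- make_resting_file(beats20)
  qc20 <- resting_file_qc(f20)
  expect_equal(qc20$fraction_filtered, 0.20)
  expect_true(qc20$accepted)

  beats21 <- beats20
  beats21[2] <- 25                        # 121/600 > 20%
  qc21 <- resting_file_qc(make_resting_file(beats21))
  expect_false(qc21$accepted)
  expect_equal(qc21$reason, "over_filtered")

  expect_error(resting_file_qc(make_activity_file(120)),
               class = "fitloop_mode_error")
  empty <- am_file("u01", "2015-03-02", "07:15:00", "resting",
                   data.frame(t_offset = numeric(0), ax = numeric(0),
                              ay = numeric(0), az = numeric(0),
                              hr = integer(0)))
  expect_equal(resting_file_qc(empty)$reason, "empty")
})

test_that("QC is a pure function of file content", {
  f <- make_resting_file(c(rep(62, 500), rep(25, 100)))
  expect_identical(resting_file_qc(f), resting_file_qc(f))
  a <- make_activity_file(85)
  expect_identical(activity_file_qc(a), activity_file_qc(a))
})

test_that("daily resting HR is the mean over the centred 5-minute window", {
  expect_equal(daily_hrrest(make_resting_file(64)), 64)

  # 70 bpm for minutes 0-5, 60 bpm for minutes 5-10: window mean is 65
  halves <- c(rep(70, 300), rep(60, 300))
  expect_equal(daily_hrrest(make_resting_file(halves)), 65)

  # 8-minute file: window is minutes 1.5-6.5
  eight <- c(rep(80, 90), rep(64, 300), rep(80, 90))  # 64 exactly in window
  expect_equal(daily_hrrest(make_resting_file(eight, minutes = 8)), 64)

  expect_error(daily_hrrest(make_activity_file(120)),
               class = "fitloop_mode_error")
})

test_that("daily resting HR of a constant file equals that constant", {
  for (minutes in c(7.5, 8, 9, 10)) {
    f <- make_resting_file(61, minutes = minutes)
    expect_true(resting_file_qc(f)$accepted)
    expect_equal(daily_hrrest(f), 61)
  }
})

test_that("activity-file QC applies the no-HR and mean-HR rules", {
  expect_true(activity_file_qc(make_activity_file(120))$accepted)
  expect_true(activity_file_qc(make_activity_file(80))$accepted)
  qc79 <- activity_file_qc(make_activity_file(79))
  expect_false(qc79$accepted)
  expect_equal(qc79$reason, "low_mean_hr")
  qc0 <- activity_file_qc(make_activity_file(0))  # hr channel all zero
  expect_equal(qc0$reason, "no_hr")
  expect_error(activity_file_qc(make_resting_file(62)),
               class = "fitloop_mode_error")
})

test_that("sessions are segmented into warm-up, endurance and cool-down", {
  s30 <- segment_and_summarize(make_activity_file(130, minutes = 30))
  expect_equal(s30$total_min, 30)
  expect_equal(s30$endurance_min, 20)
  expect_equal(s30$endurance_mean_hr, 130)

  s9 <- segment_and_summarize(make_activity_file(130, minutes = 9))
  expect_equal(s9$endurance_min, 0)
  expect_true(is.na(s9$endurance_mean_hr))

  # endurance mean only over endurance beats
  mixed <- c(rep(100, 300), rep(140, 1200), rep(90, 300))
  expect_equal(
    segment_and_summarize(make_activity_file(mixed, minutes = 30))$endurance_mean_hr,
    140)
})

test_that("feedback emits ordered phase events and zone-entry events", {
  p <- prescription_record("2015-03-02", "mandatory", 20, 115, 128, 1)
  inside <- make_activity_file(c(rep(120, 300), rep(121, 1200), rep(118, 300)))
  ev <- feedback_events(inside, p)
  expect_identical(ev$kind, c("phase_end_warmup", "phase_end_endurance",
                              "phase_end_cooldown"))
  expect_equal(ev$t_offset, c(300, 1500, 1800))

  # one 2-minute excursion above the zone -> exactly one above_zone event
  hrs <- c(rep(120, 300), rep(121, 300), rep(140, 120), rep(121, 780),
           rep(118, 300))
  ev2 <- feedback_events(make_activity_file(hrs), p)
  expect_equal(sum(ev2$kind == "above_zone"), 1)
  expect_equal(sum(ev2$kind == "below_zone"), 0)

  # dipping below zone_lo during endurance fires below_zone once
  hrs3 <- c(rep(120, 300), rep(100, 600), rep(121, 600), rep(118, 300))
  ev3 <- feedback_events(make_activity_file(hrs3), p)
  expect_equal(sum(ev3$kind == "below_zone"), 1)

  expect_error(
    feedback_events(inside, prescription_record("2015-03-02", "rest", 0, 0, 0, 1)),
    class = "fitloop_validation_error")
})
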