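# The hard-coded progression table is this suite's oracle for the engine.
TABLE1 <- data.frame(
  week = 1:12,
  pct_lo = c(40, 40, 45, 45, 50, 50, 55, 55, 60, 60, 65, 65),
  pct_hi = c(50, 50, 55, 55, 60, 60, 65, 65, 70, 70, 75, 75),
  endurance_min = c(20, 25, 25, 30, 30, 35, 35, 40, 40, 45, 45, 50)
)

test_that("the bundled framework byte-matches the progression table", {
  fw <- default_framework()
  expect_equal(fw$week, TABLE1$week)
  expect_equal(fw$pct_lo, TABLE1$pct_lo)
  expect_equal(fw$pct_hi, TABLE1$pct_hi)
  expect_equal(fw$endurance_min, TABLE1$endurance_min)
  expect_equal(fw$sessions_min, rep(3L, 12))
  expect_equal(fw$sessions_max, c(3L, rep(4L, 11)))
})

test_that("Karvonen zones evaluate and round half-up", {
  z <- target_hr_zone(65, 190, 40, 50)
  expect_identical(c(z$lo_bpm, z$hi_bpm), c(115L, 128L))  # 127.5 -> 128
  expect_identical(target_hr_zone(60, 190, 50, 100)$hi_bpm, 190L)
  expect_error(target_hr_zone(190, 65, 40, 50),
               class = "fitloop_validation_error")
  expect_error(target_hr_zone(65, 190, 50, 40),
               class = "fitloop_validation_error")
})

test_that("zones are strictly increasing in resting HR (fixed max and band)", {
  withr::local_seed(3)
  for (i in 1:20) {
    hrmax <- runif(1, 160, 210)
    pcts <- sort(runif(2, 30, 90))
    h1 <- runif(1, 45, 75)
    h2 <- h1 + runif(1, 2, 15)
    z1 <- target_hr_zone(h1, hrmax, pcts[1], pcts[2])
    z2 <- target_hr_zone(h2, hrmax, pcts[1], pcts[2])
    expect_true(z1$lo_bpm <= z2$lo_bpm && z1$hi_bpm <= z2$hi_bpm)
    # strict on the unrounded scale; allow rounding ties of at most 1 bpm
    expect_true(z2$lo_bpm - z1$lo_bpm >= floor((h2 - h1) * (1 - pcts[2] / 100)) - 1)
  }
})

test_that("effective resting HR follows the fallback chain", {
  profile <- test_profile(baseline = 70)
  ledger <- setNames(
    c(62, 64, 63, NA, 63, NA, 64),
    format(profile$start_date + 0:6))
  expect_equal(weekly_effective_hrrest(ledger, 2, profile), 63.2)

  # no data in the immediately preceding week: most recent prior week wins
  ledger2 <- setNames(c(61, rep(NA, 13)), format(profile$start_date + 0:13))
  expect_equal(weekly_effective_hrrest(ledger2, 3, profile), 61)

  # no uploads ever: baseline; no baseline either: the 65 bpm default
  expect_equal(weekly_effective_hrrest(numeric(0), 1, profile), 70)
  nobase <- participant_profile("u02", "M", NA, 190, profile$start_date)
  expect_equal(weekly_effective_hrrest(numeric(0), 1, nobase), 65)
})

test_that("the weekly pattern has 3 mandatory days, optional day 6, no 3-day runs", {
  for (w in 1:12) {
    sched <- schedule_week(w)
    expect_identical(sched[6], "optional")
    expect_identical(sum(sched == "mandatory"), 3L)
    active <- sched != "rest"
    runs <- rle(c(active, active))  # wrap around week boundaries
    expect_true(max(runs$lengths[runs$values]) <= 2)
  }
})

test_that("day-1 prescription matches the framework and the Karvonen zone", {
  config <- run_config()
  state <- new_intervention_state(test_profile(), config)
  p <- next_prescription(state, test_profile()$start_date, config)
  expect_identical(p$kind, "mandatory")
  expect_identical(p$endurance_min, 20L)
  expect_identical(c(p$zone_lo_bpm, p$zone_hi_bpm), c(115L, 128L))
  expect_identical(c(p$warmup_min, p$cooldown_min), c(5L, 5L))

  expect_identical(next_prescription(state, test_profile()$start_date + 1,
                                     config)$kind, "rest")
  expect_error(next_prescription(state, test_profile()$start_date + 84,
                                 config), class = "fitloop_window_error")
  expect_error(next_prescription(state, test_profile()$start_date - 1,
                                 config), class = "fitloop_window_error")
})

test_that("the compliance gate holds below 70% and advances at exactly 70%", {
  config <- run_config()
  # plan week 2 (25 min endurance): recommended 75; 52 completed -> hold
  st <- drive_engine(c(1, 52 / 75), config = config)
  expect_identical(st$history$decision, c("advance", "hold"))
  expect_equal(st$history$recommended_min[2], 75)
  expect_equal(st$history$completed_min[2], 52)
  expect_identical(st$plan_week, 2L)

  # exactly 70% advances ("less than 70%" fails the check)
  st70 <- drive_engine(c(1, 0.70))
  expect_identical(st70$history$decision[2], "advance")

  st0 <- drive_engine(c(1, 0))
  expect_identical(st0$history$decision[2], "hold")

  # week 1 always advances, even with nothing completed
  st1 <- drive_engine(0)
  expect_identical(st1$history$decision, "advance")
})

test_that("a downloaded optional session raises the recommended total", {
  config <- run_config()
  profile <- test_profile()
  state <- new_intervention_state(profile, config)
  for (dow in 1:7) {  # week 1, perfect
    state <- advance_day(state, profile$start_date + dow - 1,
                         list(endurance_min = if (dow == 1) 60 else 0), config)
  }
  # week 2: optional downloaded, 52 min completed: 52/100 < 0.70 -> hold
  for (dow in 1:7) {
    state <- advance_day(state, profile$start_date + 7 + dow - 1, list(
      endurance_min = if (dow == 1) 52 else 0,
      optional_downloaded = dow == 6), config)
  }
  expect_equal(state$history$recommended_min[2], 100)
  expect_identical(state$history$decision[2], "hold")
})

test_that("under perfect compliance the engine replays the table week by week", {
  st <- drive_engine(rep(1, 12))
  expect_identical(st$history$plan_week, 1:12)
  expect_identical(st$history$decision, rep("advance", 12))
  expect_equal(st$history$recommended_min, 3 * TABLE1$endurance_min)
  # zones each week are the Karvonen evaluation of that week's table row
  for (w in 1:12) {
    z <- target_hr_zone(st$history$effective_hrrest[w], 190,
                        TABLE1$pct_lo[w], TABLE1$pct_hi[w])
    expect_identical(st$history$zone_lo[w], z$lo_bpm)
    expect_identical(st$history$zone_hi[w], z$hi_bpm)
  }
})

test_that("plan week is monotone, bounded by calendar week and capped at 12", {
  withr::local_seed(9)
  for (i in 1:5) {
    st <- drive_engine(runif(12))
    pw <- st$history$plan_week
    expect_true(all(diff(pw) >= 0))
    expect_true(all(pw <= st$history$calendar_week))
    expect_true(all(pw <= 12))
  }
})

test_that("the calendar-week-12 override forces the field test", {
  # zero compliance after week 1: plan stalls at 2 until the override
  st <- drive_engine(c(1, rep(0, 11)))
  expect_identical(st$history$plan_week[11], 2L)
  expect_identical(st$history$plan_week[12], 12L)

  # the first activity day of calendar week 12 is the 12-minute field test
  config <- run_config()
  profile <- test_profile()
  state <- drive_engine(c(1, rep(0, 10)))  # state poised at week 12
  eft_date <- profile$start_date + 77  # day 78
  p <- next_prescription(state, eft_date, config)
  expect_identical(p$kind, "eft")
  expect_identical(p$endurance_min, 12L)
  # remaining week-12 activity days use the week-12 row
  p2 <- next_prescription(state, eft_date + 2, config)
  expect_identical(p2$kind, "mandatory")
  expect_identical(p2$endurance_min, 50L)
})

test_that("advance_day increments weeks and rejects out-of-order dates", {
  config <- run_config()
  profile <- test_profile()
  state <- new_intervention_state(profile, config)
  for (d in 0:6) state <- advance_day(state, profile$start_date + d, config = config)
  expect_identical(state$calendar_week, 2L)
  expect_error(advance_day(state, profile$start_date + 9, config = config),
               class = "fitloop_sequence_error")
  expect_error(advance_day(state, profile$start_date + 6, config = config),
               class = "fitloop_sequence_error")
})
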