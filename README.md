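# fitloop

Closed-loop personalized physical activity prescription from wearable
monitor data.

fitloop is for exercise scientists, digital-health researchers and
clinicians who want to run — or simulate — a twelve-week walking/running
intervention in which a wearable activity monitor (AM) drives the plan.
The loop it implements:

1. The AM records triaxial acceleration and beat-wise instantaneous heart
   rate, in a binary dialect this package defines (activity sessions and
   10-minute supine resting recordings).
2. Signal quality control rejects unusable files (resting recordings
   shorter than 7.5 min or with > 20% of beats filtered by a 10-beat
   moving-average rule; activity sessions with no heart rate or a session
   mean below 80 bpm) and extracts a daily resting heart rate from the
   middle five minutes of each accepted resting recording.
3. A rule-based engine issues one prescription per day from a 12-week
   progression table. Intensity is a Karvonen heart-rate-reserve zone,

       HR_target = HR_rest + (p/100) * (HR_max − HR_rest),

   re-personalized weekly from the measured resting HR. The plan advances
   to the next week only when credited endurance minutes reach ≥ 70% of
   the recommendation; calendar week 12 always brings a 12-minute
   walk/run exercise field test.
4. Exercise dose is scored as training impulse,

       TRIMP = t · HRr · e^(k·HRr),   k = 1.92 (men), 1.67 (women),

   for both recommended and completed sessions.
5. Administrative triggers watch the data flow: a reminder after 3 days
   without resting data, a survey after 7 upload-free days, an
   administrator notification after 3 days without a prescription
   download, plus four fixed milestone notifications.
6. A synthetic-participant simulator (physiology + compliance profiles)
   replaces the device and the human, so the whole loop runs and is
   tested as software.

## Worked example

```r
library(fitloop)

# A zone for a participant with resting HR 65, max HR 190, week-1 band 40-50%:
z <- target_hr_zone(65, 190, 40, 50)
c(z$lo_bpm, z$hi_bpm)
#> [1] 115 128            # 127.5 rounds half-up to 128

# The dose of a 20-minute endurance session at the band midpoint (HRr 0.45):
trimp(20, 0.45, "M")
#> [1] 21.35369           # 9 * exp(1.92 * 0.45)

# Day 1 prescription for that participant:
state <- new_intervention_state(participant_profile("u01", "M", 65, 190, "2020-01-06"))
next_prescription(state, "2020-01-06")
#> 2020-01-06 week 1: mandatory, 20 min endurance, zone 115-128 bpm

# Run the full 12-week loop with the fully adherent synthetic participant:
pp <- preset_profiles("adherent")
run <- run_closed_loop(pp$phys, pp$compliance, seed = 11)
head(run$dose[, c("week", "plan_week", "recommended_min", "completed_min",
                  "recommended_trimp", "completed_trimp", "decision")], 4)
#>   week plan_week recommended_min completed_min recommended_trimp completed_trimp decision
#> 1    1         1              80            80            85.415          90.543  advance
#> 2    2         2             100           100           106.768         106.142  advance
#> 3    3         3             100           100           130.585         129.298  advance
#> 4    4         4             120           120           156.702         163.191  advance
```

Each row is one calendar week: the participant was asked for
`recommended_min` endurance minutes (3 mandatory sessions plus a
downloaded optional one), completed all of them, trained close to the
zone midpoint (completed TRIMP ≈ recommended TRIMP), and the plan
advanced. With `preset_profiles("sporadic")` the plan stalls around week
4, reminder/survey events appear in `run$store$events`, and the week-12
override still schedules the field test.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fitloop", package = "fitloop"))')
Rscript "$CLI" simulate --scenario scenario.dcf --out store/   # run a synthetic scenario
Rscript "$CLI" ingest --store store/ --date 2020-01-06 u01_20200106_071500_R.amb
Rscript "$CLI" prescribe --store store/ --date 2020-01-07      # writes the binary record
Rscript "$CLI" report --store store/                           # weekly dose table
Rscript "$CLI" monitor --store store/ --date 2020-01-06        # daily log + triggers
```

A scenario file is DCF text, e.g. `preset: adherent`, `seed: 5`. Exit
codes: 0 success, 2 usage error, 3 data error.

## More

The methods vignette (`vignettes/closed-loop-prescription.Rmd`) documents
the model, every tunable threshold and its default, what the simulator
does and does not emulate, and the package's design decisions.
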