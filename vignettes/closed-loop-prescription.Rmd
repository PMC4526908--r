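---
title: "Closed-loop personalized activity prescription: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop personalized activity prescription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitloop)
```

# The problem

Sedentary, low-cardiovascular-risk adults benefit from a gradual,
individually dosed introduction to walking and running, but fixed
twelve-week plans ignore two things a wearable monitor can measure daily:
whether the person actually completed the prescribed sessions, and how
their cardiovascular system is adapting (visible as a slow decline in
resting heart rate). fitloop implements a complete closed loop around
those two signals: a wearable activity monitor (AM) records triaxial
acceleration and beat-wise instantaneous heart rate; quality-controlled
recordings feed a rule-based engine that writes the next day's
prescription; and administrative triggers watch the data flow for signs of
drop-out. A synthetic-participant simulator stands in for the device and
the human, so the entire loop is testable as software.

# The intervention model

## Progression framework

The plan is a twelve-row table (one row per *plan week*): three mandatory
sessions per week plus an optional fourth on day six, an endurance
duration that grows from 20 to 50 minutes, and an intensity band that
grows from 40–50% to 65–75% of heart-rate reserve, alternating duration
and intensity increments roughly biweekly. Each session is
warm-up (5 min) + endurance (variable) + cool-down (5 min); recommended
durations count the endurance phase only. The table ships as an editable
TSV (`default_framework()`), so other populations can be re-parameterized,
and the weekly day pattern is
`mandatory, rest, mandatory, rest, mandatory, optional, rest` — the unique
evenly spaced pattern that offers the optional day on day six while never
scheduling more than two consecutive activity days.

## Target zones (Karvonen / heart-rate reserve)

Intensity is prescribed as a heart-rate zone
$$\mathrm{HR}_{target} = \mathrm{HR}_{rest} + \frac{p}{100}\,(\mathrm{HR}_{max} - \mathrm{HR}_{rest})$$
evaluated at both band ends and rounded half-up to integer bpm, because
the monitor's in-session feedback compares integer beats per minute. Zones
are re-personalized every week using the **effective resting HR**: the
mean of the previous calendar week's accepted daily resting values,
falling back to the most recent earlier week, then to the baseline
measurement, then to 65 bpm when nothing was ever measured (the value the
original system used to avoid algorithm errors).

## Compliance gating

At the end of every calendar week from week two onward, the plan advances
only if credited endurance minutes reach at least 70% of the recommended
total (three endurance durations, plus a fourth if the optional
prescription was downloaded that week). Equality at 70% advances — the
rule is "*less than* 70% holds". Week one always advances. Two further
rules govern crediting: sessions are allocated to the *recording* date
from the filename, and files uploaded after their week has rolled over are
stored but never retro-credited. Regardless of compliance, calendar week
12 forces plan week 12 and its first activity day becomes a 12-minute
walk/run exercise field test (EFT), so every participant reaches the
fitness assessment.

# Signal processing

## Beat encoding

The monitor-file dialect stores heart rate per fixed-rate row (10 rows/s)
with `hr = 0` meaning *no beat detected at this row*; a beat is a row with
a nonzero value. All beat-wise rules (filtering, means) operate on those
rows. Stored beats must lie in 20–250 bpm; physiologically implausible
values inside that range are handled by filtering, not by the format.

## Resting-beat filtering

A beat is removed when it is outside 30–220 bpm or deviates from the
trailing 10-beat moving average of the raw series by more than 25%
(relative). The 25% threshold is this package's design choice: the
original description says a 10-beat moving average "removes aberrant
beats" without stating the criterion, and no parameter-free reading
exists; both the window and the threshold are exposed in `run_config()`.
Two consequences worth knowing:

* **Boundary semantics are literal.** Files shorter than 7.5 minutes are
  rejected; exactly 7.5 minutes is accepted. More than 20% filtered is
  rejected; exactly 20% is accepted. Activity sessions with mean HR below
  80 bpm are excluded; exactly 80 is accepted.
* **Single-pass filtering is not idempotent at the window start.** While
  the moving average is warming up (the first partial windows), an
  artifact is largely its own reference, survives the pass, and would
  cause a second pass to discard clean neighbours. The property tests
  therefore place injected artifacts after the warm-up region, where
  filtering genuinely is idempotent. Iterating the filter to a fixed
  point would change the meaning of `fraction_filtered`, so we keep the
  single pass.

## Daily resting HR

The daily value is the mean of clean beats in the 5-minute window centred
on the file midpoint (minutes 2.5–7.5 of a 10-minute recording). The
original rule is stated only for 10-minute files; we generalize to any
accepted length ≥ 7.5 minutes by keeping the window centred. The window is
half-open (`[centre − 150 s, centre + 150 s)`) so that beats landing
exactly on the upper boundary are not double-weighted relative to the
lower one.

## Session segmentation and feedback

Phases are cut by recorded time (first 5 minutes warm-up, last 5 cool-down)
because the dialect carries no phase markers. The in-session light
feedback is reproduced as an event stream: phase-end events at the
prescribed phase boundaries, and one `above_zone`/`below_zone` event per
*entry* of the trailing 5-beat moving average into violation during
endurance.

# Dose quantification (TRIMP)

Exercise dose is the training impulse
$$\mathrm{TRIMP} = t \cdot \mathrm{HRr} \cdot e^{k\,\mathrm{HRr}},$$
with $t$ the endurance minutes, $\mathrm{HRr}$ the heart-rate-reserve
ratio and $k = 1.92$ (men) or $1.67$ (women). The *recommended* ratio is
the band midpoint over 100 (0.45 for a 40–50% band). For *completed*
sessions the package defaults to the reserve reading
$(\bar{\mathrm{HR}}_{end} - \mathrm{HR}_{rest}) / (\mathrm{HR}_{max} -
\mathrm{HR}_{rest})$, clipped to $[0, 1.5]$. The source text literally
says the completed ratio is the endurance mean *divided by* the day's
resting HR; that reading yields values near 2 that are dimensionally
incommensurate with the recommended 0.45, so it is preserved only behind
`hrr_mode = "literal"` and the reserve reading is the default. Fitness
estimation from the field-test distance is plug-in only
(`estimate_vo2peak()`): the equation the original work cites is not
reproduced in it, and shipping a guessed formula would fabricate
provenance.

# Administrative monitoring

The store is a set of plain delimited-text tables (days, files, sessions,
events) emulating the original relational database. Trigger events are
emitted to the event log rather than e-mailed: a reminder on the 3rd
consecutive day without an accepted resting value (resetting only on
accepted resting uploads, consistent with its cause), a survey on the 7th
consecutive day without *any* upload (any upload resets), and an
administrator notification after 3 consecutive days without a
prescription download ("multiple days" is unquantified in the source;
3 is the configurable default). Each trigger fires once per streak and
re-arms only after the condition clears, matching the discrete reminders
the original feasibility narrative describes. Four milestone
notifications are fixed: account creation, intervention start, the day
before the EFT, and conclusion.

# The simulator: what it emulates and what it does not

`simulate_resting_file()` draws a true daily resting HR
$\mathrm{HR}_{rest,0} + \mathrm{drift}\cdot d/7 + \varepsilon_d$ (day
noise sd = `hr_noise_sd`), scatters beats around it with the same sd, and
injects artifact beats (spikes 120–200, drops 30–45 bpm) at
`aberrant_rate`. `simulate_activity_file()` ramps HR from rest to
`zone midpoint + zone_bias × zone width` over the warm-up, holds a
first-order autocorrelated process (coefficient 0.9) around that target
during endurance — so the 5-beat moving-average feedback sees realistic
excursions — and decays exponentially during cool-down. Beat arrival
times integrate the instantaneous rate, so beat counts are
physiological. Accelerations are cosmetic gait-like magnitudes: quality
control never reads them, and no claim of validated gait simulation is
made.

Two presets bracket the observed behaviours: `"adherent"` (completes
everything, daily resting uploads, slow negative drift) and `"sporadic"`
(full adherence for three weeks, then 35% completion, occasional one-day
upload lag, and a no-computer-access blackout over weeks 9–12). The drift
magnitudes are illustrative — the original study reports only a downward
trend, not a rate. Because the blackout blocks prescription downloads,
the sporadic preset cannot complete the field test, unlike the real
second subject who did; the preset reproduces the stall-and-reminders
narrative, not that detail. A green simulator test therefore establishes
that the *rules* compose correctly, not that the generator reproduces any
subject's field data.

```{r closed-loop}
pp <- preset_profiles("adherent")
run <- run_closed_loop(pp$phys, pp$compliance, seed = 11)
run$history[, c("calendar_week", "plan_week", "decision",
                "recommended_min", "completed_min")]
```

# Numerical and degenerate-input choices

* Zone bpm rounding: half-up (`floor(x + 0.5)`), so `127.5 -> 128`.
* The 70% gate compares with a `1e-9` absolute slack so that exact
  equality at the boundary advances despite binary floating point.
* Empty recordings are flagged `empty` and dropped at ingest; a resting
  file whose beats are all filtered has `fraction_filtered = 1` and is
  rejected as `over_filtered`.
* Files of 10 recorded minutes or less have no endurance phase
  (`endurance_min = 0`, endurance mean absent).
* All randomness flows from a single seed; seeded helpers restore the
  caller's RNG state (`with_seed()`), and two runs with the same seed are
  byte-identical through to the text store.
* The binary dialect (32-byte header + 11-byte rows, CRC-32; 16-byte
  prescription records, CRC-8) is a reproducibility stand-in fixed by this
  package: the original device format was never published, so tests are
  bit-exact against this dialect rather than faithful to unknown firmware.

# Known limitations

* Accelerometry is carried, validated for range, and otherwise unused —
  no step counting or activity classification.
* Post-exercise heart-rate-recovery analysis is out of scope (the
  original work names it as a goal without a method).
* The effective resting HR for a new week is computed from values known
  at the rollover; a resting file for a past date that arrives later
  updates the store but not a zone already issued.
* `weekly_effective_hrrest()` and the compliance gate assume 7-day
  calendar weeks anchored at the start date; partial first weeks are not
  modelled.
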