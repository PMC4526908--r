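Package: fitloop
Title: Closed-Loop Personalized Physical Activity Prescription from Wearable Monitor Data
Version: 0.1.0
Authors@R: person("Fitloop", "Maintainers", email = "maintainers@fitloop.invalid", role = c("aut", "cre"))
Description: Tools for running and simulating a closed-loop, twelve-week
    walking/running intervention driven by a wearable activity monitor.
    Parses and writes a binary monitor-file dialect (triaxial acceleration
    plus beat-wise instantaneous heart rate), applies signal quality control
    and resting-heart-rate extraction, generates daily personalized
    prescriptions with Karvonen heart-rate-reserve target zones and
    compliance-gated weekly progression, scores exercise dose as training
    impulse (TRIMP), emits administrative monitoring events (reminders,
    surveys, milestone notifications), and includes a synthetic-participant
    simulator so the entire loop is testable without a device or subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
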