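Package: glucowear
Title: Synchronized CGM and Wearable Activity Analytics for Remote Diabetes Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ingests continuous glucose monitoring (CGM) traces and wearable
    activity-tracker data (heart rate, per-minute steps, METs, recorded
    exercise sessions), synchronizes the streams onto a common display grid
    with gap-aware linear interpolation, computes the consensus CGM metric
    suite (wear time, mean glucose, time in range, time below and above
    range) and physical-activity metrics (tracker wear time, epoch-based
    intensity classification, daily moderate-to-vigorous activity,
    exercise-guideline adherence) per review period, raises
    exercise-dysglycemia and population-level flags for clinician review,
    and assembles a prioritized patient review table. Includes a
    deterministic synthetic patient simulator with ground truth so the full
    pipeline is testable without device data, and a command-line interface
    for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
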