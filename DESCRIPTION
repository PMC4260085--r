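Package: engagelog
Title: Engagement Log Analysis and Visualization for Web-Based Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms raw event logs from web-based (e-health) intervention
    platforms into engagement views. Maps event identifiers (URLs) to content
    labels or feature categories via a curated key file, segments per-user
    event streams into sessions by an inactivity threshold, and computes four
    visualization-backing tables: per-user navigation traces, per-cohort usage
    stripe calendars, per-session start/finish content pages, and next-action
    transition matrices. Includes ggplot2 renderers for each view, a synthetic
    cohort generator with known ground truth for testing, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
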