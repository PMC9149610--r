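Package: nivflow
Title: Executable Workflow Engine for Titration of Long-Term Non-Invasive
    Ventilation in Hypercapnic COPD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A rule-based decision- and workflow-support engine for initiating
    and titrating long-term non-invasive ventilation (NIV) in stable
    hypercapnic COPD patients. Implements three interlocking clinical
    processes as deterministic finite-state machines: first initiation (INI),
    day-time titration (TDT) and night-time titration (TNT), together with
    blood-gas safety gates (hypoxemia, acidosis, alkalosis), a four-item
    comfort questionnaire driving ventilator adjustments, and a PaCO2 trend
    criterion for nocturnal adequacy. A session engine orchestrates the
    processes on an abstract minute clock, records an append-only audit
    event log, and supports lossless JSON persistence and deterministic
    replay. A seeded virtual-patient simulator closes the loop so that every
    branch of the decision logic is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
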