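Package: edflow
Title: Discrete-Event Simulation of Emergency-Department Patient Flow and
    Physician Scheduling Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event simulator of emergency-department patient flow
    for moderate- and low-acuity (triage Level III/IV) patients. Patients
    arrive by a weekly-cyclic non-homogeneous Poisson process, receive an
    initial physician consultation, may undergo a sequence of diagnostic
    examinations on capacitated devices, and return for a follow-up
    consultation once all reports are available. The package implements three
    physician-allocation policies (Initial-First, Alternating 1:1, and a
    Slack-Based dynamic rule that escalates patients approaching their
    clinical waiting-time target), a two-stage grid search over the slack
    tolerances, a KPI layer (waiting times, delay rates, service levels,
    utilizations), and paired-comparison statistics under common random
    numbers. The event engine is written in C++ for speed; all sampling is
    done in R so that random-number streams are policy-independent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
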