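Package: driftdive
Title: Drift-Dive Detection and Buoyancy Trajectories from Summarized
    Seal Dive Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical detection of drift dives and estimation of
    buoyancy (drift-rate) time series from broken-stick-summarized
    time-depth profiles of deep-diving marine mammals.  Implements the
    on-board broken-stick abstraction (BSA) of high-resolution dives, a
    reverse broken-stick algorithm (RBSA) that recovers the inflection
    point selection order from a transmitted 6-point summary, per-group
    dive-shape rules locating the passive drift segment, sequential
    threshold criteria rejecting non-drift dives, and a Bayesian
    state-space trajectory filter with per-dive binary inclusion
    variables fitted by MCMC (JAGS).  A synthetic trip generator with
    known labels, drift segments, and a daily buoyancy trajectory
    provides ground truth for validation, together with bias and daily
    averaged drift-rate (ODDR/SDDR) error metrics.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
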