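Package: cardiorep
Title: Repetition-Range Probability Analysis of Cardiac Dynamics from
    Holter Recordings
Version: 0.1.0
Authors@R:
    person("Harmonyk", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Summarizes beat-level Holter heart-rate data into per-value
    repetition profiles, filters them by repetition-count ranges
    (1000-2000 and 2001-3000), forms the within-range probability
    distribution over 5-bpm heart-rate groups, and sums the two largest
    probabilities into a single statistic per range.  A rule-based
    classifier maps these features to normal, chronic, acute, or
    pacemaker cardiac dynamics, with an audit trail for every band
    predicate.  Includes diagnostic-accuracy evaluation (per-class
    sensitivity, specificity, Cohen's kappa), a seeded synthetic-data
    generator that realizes 21-hour-like recordings from target
    repetition profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
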