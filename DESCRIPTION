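Package: racestop
Title: Simulation and Analysis of the Picture-Word Interference Stop-Signal Task
Version: 0.1.0
Authors@R: person("racestop", "maintainers", email = "racestop@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing a picture naming
    experiment in which semantically related or unrelated distractor words are
    superimposed on target pictures and a visual stop-signal occasionally
    requires the vocal response to be withheld. Provides a constrained
    pseudorandomized trial-schedule builder with a validator, a mechanistic
    simulator of the independent horse-race model (fixed stop-signal delays and
    one-up/one-down tracking), trial classification and standard-deviation
    outlier trimming, stop-signal reaction time estimation with the integration
    and mean methods per delay and distractor condition, sign-flip permutation
    inference for within-participant effects, and a calibrated synthetic cohort
    generator with ground-truth sidecars for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
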