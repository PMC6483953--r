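Package: edahab
Title: Electrodermal Habituation Scoring and Auditory Detection Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for event-related skin conductance response (SCR) analysis
    of auditory habituation experiments: zero-phase Butterworth filtering and
    first-derivative peak/trough SCR detection, trial scoring against
    amplitude and latency criteria, trials-to-habituation and non-responder
    classification, block-magnitude slope analysis, a descending/ascending
    method-of-limits staircase for auditory detection thresholds with
    simulated psychometric observers, and the accompanying statistical stage
    (normality screening by skewness/kurtosis z-scores, IQR-fence outlier
    winsorization, one-way and mixed repeated-measures ANOVA, Cohen's d,
    Pearson/Spearman correlations, Bonferroni correction). A synthetic-data
    module generates stimulus schedules, skin-conductance traces with known
    ground-truth SCRs, psychometric observers, and two-group cohorts so the
    full pipeline can be exercised and validated without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
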