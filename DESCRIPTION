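Package: digiphen
Title: Digital Phenotyping of Smartphone and Wearable Event Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives behavioural features from raw smartphone and wearable
    event streams collected in remote-monitoring studies: active phone use
    sessions from phone status logs, response latencies to social and
    communication app notifications (with sleep-interval exclusion),
    questionnaire notification response latencies and between-questionnaire
    intervals, within-session ambient light variability, step counts during
    active phone use, and daily counts of newly appearing apps. Provides
    two-group comparisons with linear mixed models and t tests, a
    variance-component effect size for mixed models, the IQR proximity rule
    for outlier removal, a sensitivity analysis excluding high-variability
    participants, and a deterministic synthetic cohort generator whose
    derived features are moment-matched to configurable group-level targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
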