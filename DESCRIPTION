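Package: seqmonitor
Title: Sequential Monitoring of Two-Arm Binary Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the evidence in a two-arm trial with a
    binary outcome evolves as participants accrue. Recomputes the odds ratio,
    Wald confidence interval and two-sided P value at every interim look and
    detects significance-line crossings; extends an observed trial by
    resampling its own responders with replacement; and runs a Bayesian group
    sequential monitor in which a skeptical normal prior on the log odds
    ratio is updated at each look and prespecified posterior-probability
    criteria decide between continuing, stopping for success, and stopping
    for futility. Includes a seedable generator of accrual-ordered synthetic
    trials (with optional attrition and regime drift) and Monte-Carlo
    operating characteristics contrasting naive P-value peeking with the
    Bayesian stopping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    patchwork,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
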