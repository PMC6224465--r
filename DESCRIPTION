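Package: hyperdisc
Title: Hyperbolic Delay Discounting: Choice Design, Model Fitting and
    Simulated Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for within-subject intertemporal-choice experiments on
    the magnitude and hidden-zero effects. Constructs binary choice sets
    from percent-difference tiers with balanced delays, fits a hyperbolic
    discounting model (V = r / (1 + k t)) with a softmax choice rule by
    multi-start maximum likelihood, derives indifference-point (k_eq)
    diagnostics such as correct-choice rates and smaller-sooner choice
    probabilities, and runs study-level statistics: type-III mixed ANOVA
    with generalized eta squared, paired t tests, and a two-sided Fisher
    exact comparison of paired reduction proportions. A synthetic-agent
    study generator reproduces the statistical structure of a
    three-condition, three-stimulation-level design so the full pipeline
    is verifiable without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
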