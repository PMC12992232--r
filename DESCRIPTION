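Package: ahpfce
Title: AHP-FCE Evaluation of Multi-Level Indicator Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for hierarchical multi-criteria evaluation of expert
    Likert-scale surveys, combining the analytic hierarchy process (AHP,
    with principal-eigenvector weights and consistency-ratio checking),
    the entropy weight method, and fuzzy comprehensive evaluation (FCE)
    with frequency-based membership matrices. Includes hierarchical
    aggregation to composite scores with grade assignment, a robustness
    suite (weight-perturbation sensitivity, expert-resampling stability,
    Cronbach's alpha), a synthetic expert-panel generator, and a bundled
    fixture reproducing a published provincial food-safety governance
    assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
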