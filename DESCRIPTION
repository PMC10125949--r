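Package: earlyclick
Title: Early Prediction of Task Failure from Clickstream Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for investigating how early the behavioral outcome
    (failure versus success) of a time-stamped action sequence on an
    interactive task can be predicted from early-window clickstream data.
    Provides readers and preprocessing rules for timed action logs, creation
    of early-window subsets by action count or elapsed time together with
    Earliness and Utility descriptives, feature construction (tf-idf action
    weights, times to first occurrence, one-hot bi-/trigrams, activity),
    gradient-boosted tree classification with informative missingness under
    nested cross-validation with minority upsampling, gain-based feature
    importance, and a configurable synthetic clickstream generator for
    method evaluation without access to restricted assessment log data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
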