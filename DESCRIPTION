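Package: bseqlab
Title: Home-Cage Behavior-Sequence Analysis Along One Light-Dark Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests home-cage behavior-state time series (event sequences or
    minute/hour summaries), synchronizes them to the facility light/dark
    cycle, pools the 45 raw video-classifier labels into coarser behavior
    categories, derives square-root time-proportion features over nine
    light-cycle-anchored time windows, and tests for group differences with
    a PCA first-component nonparametric test, double random-forest variable
    selection with a 3-component ICA embedding, and SVM classification
    validated by two-out or holdout schemes with a permutation null and a
    binomial confidence interval for the p-value. Includes a spreadsheet
    metadata schema (master/experiment/lab) that makes projects
    machine-readable, behavior-transition context analysis, hourly activity
    summaries, cross-project pooling, and a semi-Markov synthetic recording
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    ica,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
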