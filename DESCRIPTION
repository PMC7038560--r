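Package: sixmapred
Title: Sequence-Based Prediction of DNA N6-Methyladenine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA N6-methyladenine (6mA) modification status of
    adenines from 41-nt sequence windows. Encodes each window with three
    sequence-feature families (electron-ion interaction pseudopotential
    trinucleotide features, position-specific trinucleotide propensity in
    single- and double-stranded form, and physicochemical Type-II pseudo
    k-tuple nucleotide composition), ranks features by a maximum-relevance
    maximum-distance score with incremental feature selection, and
    classifies with gradient-boosted decision trees. Includes dataset
    construction from a genome plus a site table (confidence filtering,
    window extraction, exclusion-aware negative sampling, greedy identity
    redundancy reduction), positional trinucleotide entropy profiling,
    jackknife and cross-validated evaluation, and a synthetic motif-planted
    data generator so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
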