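Package: wapriori
Title: Weighted Apriori Mining with Automatic Per-Level Minimum Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Frequent-pattern and association-rule mining for categorical
    registry tables (e.g. trauma registries) using a weighted Apriori
    algorithm: per-feature weights from information gain against an outcome
    column, itemset support weighted by the harmonic mean of member-item
    weights, and a minimum-support threshold generated automatically at
    every level of the search instead of being fixed by the user. Includes
    a classic fixed-threshold Apriori baseline for head-to-head comparison,
    a preprocessing pipeline (outlier removal, imputation, min-max
    normalisation, one-hot transaction encoding), a synthetic registry
    generator with plantable co-occurring patterns, and benchmark surfaces
    (pattern/rule counts, median rule confidence by itemset size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
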