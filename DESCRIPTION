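Package: ctrquality
Title: Registration Quality and Structural Factors in Clinical Trial Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for registry-based meta-research on
    clinical trials. Harmonizes registry exports from three dialects (AACT
    pipe-delimited, DRKS CSV, WHO ICTRP CSV) into a common trial-record table,
    deduplicates records across and within registries with an ID cascade plus a
    random-forest pairwise match classifier, classifies pre-registration and
    German structural factors (Universities of Excellence, Coordinating Centers
    for Clinical Trials), draws stratified manual-inspection samples, scores
    registration quality with an eight-category rubric operating on structured
    annotations, and fits logistic and linear regression models with
    two-standard-deviation predictor standardization. A synthetic registry
    generator with known ground truth makes every stage testable without
    registry downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringi,
    stringr,
    readr,
    lubridate,
    rlang,
    jsonlite,
    yaml,
    ranger,
    igraph,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
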