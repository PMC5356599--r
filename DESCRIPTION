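Package: reotools
Title: Individualized Differential Expression from Stable Within-Sample
    Gene-Pair Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene pairs whose within-sample relative expression
    ordering (REO) is significantly stable across a cohort of normal tissue
    samples (binomial test with Benjamini-Hochberg control), compares and
    intersects stable-pair sets across datasets and profiling platforms
    (POG and concordance scores, rank-difference diagnostics), calls
    differentially expressed genes in a single disease sample from reversed
    orderings with a Fisher's exact test (the RankComp procedure), and runs
    per-sample pathway enrichment of up- and down-regulated gene lists.
    Includes a synthetic-data generator that emulates template-ordered
    normal cohorts, platform-specific probe biases and paired tumor/normal
    profiles with planted differential expression, so the whole stack is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
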