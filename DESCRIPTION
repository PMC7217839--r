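Package: denovotrio
Title: De Novo Copy Number Variant Detection in Parent-Offspring Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control, merging and filtering of SNP-array CNV calls,
    classification of proband calls as likely de novo versus inherited in
    parent-offspring trios, annotation against neurodevelopmental risk loci
    and gene models, and cohort mutation- and carrier-rate statistics with
    exact binomial confidence intervals. Ships summary-table fixtures from a
    published ADHD trio study (305 trios, 14 de novo CNVs) so every headline
    rate is reproducible at desk scale, plus a synthetic trio simulator with
    planted truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
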