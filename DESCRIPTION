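Package: varcascade
Title: Germline Variant Prioritisation and Cost-Consequence Modelling for
    Hereditary Cancer Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a germline variant prioritisation workflow for
    whole-genome sequencing in a familial cancer setting: allele-frequency and
    variant-allele-fraction filtering of small variants with ClinVar rescue, a
    dual-caller structural/copy-number variant cascade based on reciprocal
    overlap, blacklist regions and population frequencies, reportability gates
    with VUS tiering for multidisciplinary-team review, cohort-level
    diagnostic-yield summaries, and a three-scenario cost-consequence decision
    model with marginal and one-way sensitivity analyses. Seeded synthetic-data
    generators provide reproducible inputs for every step, including a
    deterministic cohort fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    readr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
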