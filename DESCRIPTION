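Package: enorthern
Title: Electronic Northern Expression Profiling of EST-Derived TPM Tables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for "electronic Northern" analysis of gene expression from
    expressed-sequence-tag (EST) derived transcripts-per-million (TPM) tables.
    Computes percent mammary transcript abundance and the relative expression
    coefficient (mammary TPM over the geometric mean of skin and muscle TPM),
    classifies tissue-preferential expression by twofold threshold rules,
    summarizes gene interaction networks loaded from STRING-style weighted
    edge lists, and simulates multinomial EST-library sampling experiments
    with known tissue-preference structure so classifier recovery and error
    rates can be measured without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
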