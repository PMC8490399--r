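Package: thrombevo
Title: Clonal Evolution Patterns of Renal Cell Carcinoma Tumor Thrombi from
    Multi-Region Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-region whole-exome studies of renal
    cell carcinoma with venous tumor thrombus. Implements consensus retention
    of somatic variants across multiple callers (K-of-N rule), arm-level
    copy-number calling from gene-level log2 ratios by weighted averaging,
    driver-mutation matrix construction, rule-based classification of
    primary-tumor versus thrombus clonal-evolution patterns and of thrombus
    topologies, clone-tree construction with Newick export, and cohort-level
    summaries of patterns and grade discordance. Includes a synthetic
    multi-region cohort generator with known ground truth so the whole
    pipeline is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
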