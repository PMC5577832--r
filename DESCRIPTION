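Package: wsmeth
Title: Two-Group Differential DNA Methylation Analysis for Small Array Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential DNA methylation analysis tailored to very small
    two-group methylation array studies (for example three cases versus three
    controls on the Illumina EPIC or 450k platforms). Calls differentially
    methylated positions by per-probe two-group ANOVA on beta values, calls
    differentially methylated regions by sliding-window MANOVA (Hotelling's
    T-squared with the exact F transform) over gene-associated CpG-island,
    shore and shelf probes with an adjacency and effect-size filter, performs
    gene-set enrichment with a Fisher exact p-value combined with a
    rank-deviation z-score, tests methylation-expression concordance with
    two-sample t-tests and fold changes, and counts cross-platform
    replication of probe lists. Includes a fully annotated synthetic-data
    generator with a ground-truth registry so every stage can be exercised
    and calibrated without any external download, plus a single-config
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
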