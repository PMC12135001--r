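Package: sexmarker
Title: Design and Validation of Y-Specific PCR Markers for Sexing Dioecious Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to develop and evaluate multiplex PCR assays that determine
    the genetic sex of dioecious plants with XY sex chromosomes, such as
    Cannabis sativa. The package selects candidate sex-linked genes by
    Nei-Gojobori synonymous divergence between X and Y gene copies, calls
    fixed X-Y differences from one Y sequence aligned against multiple X
    haplotypes, enumerates Y-allele-anchored primer pairs under thermodynamic
    and dimer constraints, assembles a gel-resolvable multiplex panel with an
    autosomal control, predicts amplicons by mismatch-tolerant in silico PCR
    on male and female genome templates, and summarises assay outcomes as
    per-cultivar confusion statistics. A seeded simulator of XY gene systems,
    cultivar cohorts and genome templates makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
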