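Package: cloneboot
Title: Bootstrap Confidence for Clone Inference from Tumor Bulk Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clonal deconvolution of multi-sample tumor bulk sequencing data
    with bootstrap confidence on every variant assignment. Read counts at each
    variant position are resampled with replacement to produce bootstrap
    replicate datasets; clones are inferred in each replicate by a candidate
    pool / phylogeny / constrained-regression engine; near-identical bootstrap
    clones are grouped into consensus clones with per-position support; and
    metastatic cell-migration histories are inferred per replicate by
    minimum-migration parsimony and aggregated into a consensus history with
    per-path bootstrap support. Includes a tumor-evolution simulator and the
    genotype-error and migration-path accuracy metrics used to validate the
    approach.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
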