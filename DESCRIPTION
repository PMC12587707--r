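Package: epimutr
Title: Constitutional Epimutation Screening in Blood Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a cohort's blood DNA methylation beta-value matrix for
    constitutional epimutations: per-individual single-case outlier testing at
    every CpG against the rest of the cohort, Benjamini-Hochberg false discovery
    rate control, calling of runs of at least three consecutive aberrant CpGs,
    and classification of hypermethylated regions as monoallelic or mosaic from
    their carrier beta level. Companion stages link CpG-island methylation to
    gene expression (first-principal-component expression summary, per-CpG
    Pearson correlation, paired tumor-normal contrasts) and compare rare
    predicted-damaging variant burden between cases and population controls
    (consequence, REVEL and allele-frequency filtering; Fisher exact test).
    Includes a synthetic EPIC-like cohort generator with spiked epimutations so
    the whole pipeline is testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
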