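Package: putrescan
Title: Genome Mining of Bacterial Putrefaction Pathways in the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts amino-acid fermentation (putrefaction) pathways in
    annotated bacterial genomes from Pfam domain homology and genomic
    proximity of the component genes, aggregates per-strain predictions
    into a taxon-level putrefaction capability score (Pfacs), and links
    pathway capability to differentially abundant genera between healthy
    and colorectal-cancer gut cohorts. Ships a curated ten-pathway catalog
    covering nine harmful metabolites (ammonia, putrescine,
    spermidine/spermine, cresol, indole, phenol, cadaverine, hydrogen
    sulfide) and seeded synthetic-data generators so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
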