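Package: orthograft
Title: Graft Query Proteomes into Reference Gene Families and Classify
    Orthology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A genome-wide homology pipeline for newly sequenced genomes.
    Proteomes are reduced to one representative protein per gene, assigned
    to reference gene families from profile-HMM hit tables (with detection
    of chimeric gene models that fuse two families), and bundled for
    external alignment and placement tools. Family gene trees containing
    the query proteins are midpoint rooted, internal nodes are labelled as
    speciation or duplication with the species-overlap algorithm, and each
    query gene is classified against one or more reference species:
    closest homolog by patristic distance, ortholog/paralog/no-homolog
    call, one-to-X co-ortholog multiplicity, and median copy number across
    the query genomes. A duplication-loss gene-tree simulator with known
    event labels provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    Biostrings,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
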