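Package: allomum
Title: Progenitor Inference for Allopolyploid Genomes from Maximal Unique Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to nominate the progenitor lineages of an allopolyploid
    genome from whole-genome exact-match synteny. Implements a maximal unique
    match (MUM) engine over generalized suffix arrays, one-to-one filtering of
    match sets by weighted collinear chaining, per-species and cumulative
    pairwise coverage statistics over a candidate panel, a k-mer spectrum
    genome-size estimator, chlorophyll and relative-expression phenotype
    formulas, and a synthetic allotetraploid genome and read simulator used to
    validate the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
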