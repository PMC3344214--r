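Package: msatphylo
Title: Microsatellite Repeat Decomposition and Flanking-Region Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cloned microsatellite (SSR) allele sequences
    across closely related species: decomposition of alleles into a dinucleotide
    major repeat region and unique flanking regions, a parser and expander for
    the compact repeat-region notation used in locus survey tables, Weber-style
    classification into perfect, interrupted and compound repeats, construction
    of intraspecific IUPAC consensus flanking sequences by global alignment,
    cross-locus concatenation, transition/transversion censusing, Kimura
    two-parameter distances, Neighbor-joining tree inference with bootstrap
    support, and a forward-time allele-evolution simulator (stepwise-mutation
    slippage in the repeat tract, transition-biased substitutions and rare short
    indels in the flanks) for end-to-end validation. Results are returned as
    tibbles with broom-style tidy() and glance() methods and ggplot2 autoplot()
    figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
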