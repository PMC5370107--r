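Package: protminet
Title: Alignment-Free Protein Classification with Maximum Mutual-Information Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised, alignment-free classification of protein sequences
    and structures. Proteins are encoded as discrete state series (amino acids,
    or binned backbone phi/psi torsion angles computed from PDB coordinates),
    pairwise similarity is the maximum plug-in mutual information over all
    sliding-window alignments normalized by the maximum sequence entropy, and
    the resulting weighted undirected network is swept with a descending
    threshold grid; connected components at each threshold yield a nested
    classification hierarchy exportable as merge trees (JSON, Newick) and
    per-threshold partitions. Includes a seeded generator of synthetic
    sequence families and idealized backbone structures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    withr,
    bio3d,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
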