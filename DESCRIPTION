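Package: mycomine
Title: Mining Fungal Communities from Raw Host Genomic Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers and summarizes the fungal community hidden in raw
    whole-genome shotgun data of a eukaryotic host. Implements exact-match
    host-read subtraction, a seed-and-extend ungapped read aligner with
    best-stratum reporting and identity-threshold semantics, FC1/FCT
    lowest-common-taxon read assignment against ITS/LSU marker reference
    sets, identity-threshold sweeps, rarefaction richness curves,
    Bray-Curtis dissimilarity with neighbour-joining community clustering,
    and a ratio-based extrapolation of the total fungal read content from
    marker and whole-genome hit counts. A ground-truthed synthetic-data
    generator emulates a host genome plus a multi-genus fungal community
    with embedded marker regions for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    data.table,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
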