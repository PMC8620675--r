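Package: kchainr
Title: Reference-Free Repeat Discovery and Abundance Profiling from Raw
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers putative repetitive elements (kChains) directly from
    raw, unassembled sequencing reads by dense biclustering of a bipartite
    k-mer-by-read incidence graph, assembles each dense bicluster's k-mers
    into consensus repeat sequences, quantifies repeat abundance across
    samples as the median per-position read coverage, and analyses the
    resulting abundance matrix by principal-component biplot association,
    k-mer containment contamination screening, and neighbor-joining
    phylogeny over samples. Includes a synthetic multi-species study
    generator with planted repeat families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
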