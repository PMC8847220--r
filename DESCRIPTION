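Package: dnv
Title: Divided Natural Vectors for Alignment-Free Population Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free comparison of nucleotide sequences with natural
    vectors (per-base counts, mean positions and normalized second central
    moments) and their segment-wise extension, divided natural vectors.
    Includes reconstruction of per-haplotype consensus sequences from VCF
    variant calls, averaging of haplotype vectors into personal vectors and
    population centroids, Euclidean distance matrices and their summation
    across chromosomes, distance-based tree building (UPGMA, NJ, BIONJ) with
    outgroup rooting and Robinson-Foulds comparison, layered nearest-neighbor
    "natural graphs", mitogenome quality filters, and seeded simulators for
    references, diploid VCF cohorts and population-structured sequence sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
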