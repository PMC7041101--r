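Package: wgalignr
Title: Pairwise Whole-Genome Alignment and Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Aligns pairs of intra-species genome assemblies with a
    seed-chain-align strategy: local maximal exact matches are found with a
    Burrows-Wheeler/FM-index over the reference and its reverse complement,
    chained into similar regions by position-difference clustering, and the
    remaining gaps are closed with un-gapped scans or affine-gap dynamic
    programming. Variants (SNVs and indels) are read directly off the
    alignment and written as VCF; alignments are written as MAF or dot-plot
    segments. Includes a genome mutation simulator with truth sets and a
    precision/recall evaluator with tandem-repeat-aware indel matching, so
    alignment correctness can be benchmarked end to end on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
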