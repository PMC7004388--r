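Package: subtelomap
Title: Simulation, Assembly and Population Analysis of Subtelomeric
    Optical Genome Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the distal 500 kb of human chromosome
    arms with nick-label optical genome maps. The package generates in
    silico nick-site maps from reference sequences, simulates
    error-bearing single-molecule label maps of block-structured
    subtelomeric haplotypes in a diploid population, assembles molecules
    into consensus maps by overlap-layout-consensus with a sizing-error
    aware dynamic-programming aligner, anchors consensus maps to
    reference arms through one-copy DNA, measures telomeric extensions
    and telomere-adjacent gap corrections, detects paralogy blocks by
    nick-pattern matching, and tests block frequencies across
    super-populations with one-way ANOVA and Bonferroni correction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    mclust,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
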