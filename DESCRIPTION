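Package: holobinr
Title: Host Genome Recovery and Assessment for Holobiont Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and evaluating a host draft genome from a
    taxonomically mixed (holobiont) shotgun sequencing sample. Provides a
    synthetic holobiont generator (diploid host with tunable heterozygosity and
    repeat content, symbiont genomes of distinct base composition, uniform
    coverage paired reads, fragmented contigs with truth labels), canonical
    k-mer counting and coverage-spectrum analysis with three genome-size
    estimators (Lander-Waterman, Poisson mixture EM, negative binomial mixture
    least squares), composition plus abundance contig binning with host read
    recruitment, and a modified z-score framework for multi-assembly quality
    comparison across the operational criteria completeness, contiguity, and
    usefulness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    igraph,
    jsonlite,
    yaml,
    minpack.lm,
    rtracklayer,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
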