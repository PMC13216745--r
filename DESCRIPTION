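Package: preloop
Title: Contact Enrichment Scoring and Loop Calling for Micro-C and Hi-C
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of chromosome-conformation capture (Micro-C/Hi-C)
    contact maps around Polycomb response elements and other paired
    regulatory features. Implements a distance-decay-preserving shuffled
    expected model built by Metropolis partner swaps, a signed
    Kolmogorov-Smirnov k-nearest-neighbour contact-enrichment score,
    aggregate observed/expected enrichment grids around feature pairs,
    a multi-resolution scale-space loop caller calibrated against a
    gold-standard loop set by FDR scanning, anchor-pair score
    quantification, nonparametric group comparisons (Kruskal-Wallis with
    Dunn's post hoc test and Benjamini-Hochberg correction), and k-means
    clustering of signal tracks around features. A synthetic Micro-C
    generator with planted TADs, loops and coupled peak scores makes the
    whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
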