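Package: metabarmock
Title: Mock-Community COI Metabarcoding Simulation and Analysis
Version: 0.1.0
Authors@R: person("Metabarmock", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a known arthropod mock community and its biased COI
    amplicon read sets, then runs a complete metabarcoding analysis against
    the known truth: paired-read merging, quality filtering and trimming,
    distance-based assignment of reads to reference barcodes with greedy OTU
    clustering of the remainder, rarefaction with an asymptote criterion,
    diversity and evenness statistics, degenerate-primer mismatch scoring,
    and a coupon-collector model of the sequencing depth required by PCR-free
    protocols when template copy number scales with body mass.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
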