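Package: balscan
Title: Composite Likelihood Ratio Scans for Long-Term Balancing Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects genomic footprints of long-term balancing selection with
    a family of composite likelihood ratio statistics built on a mixture of a
    binomial "balanced" allele-frequency component and the genome-wide site
    frequency spectrum, weighted by an exponential decay in recombination
    distance. Supports derived and minor (folded) allele counts, polymorphism
    and substitution data, and a multiallelic extension for loci maintaining
    more than two balanced allelic classes. Includes deterministic
    overdominance equilibrium calculators, a synthetic-footprint data
    generator for calibration and testing, an exact Hardy-Weinberg
    heterozygote-excess filter for genotype QC, and a small command-line
    interface over tab-separated site and spectrum files.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
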