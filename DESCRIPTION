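Package: xshred
Title: Discovery of X-Linked Repeat CRISPR Targets and Quantification of
    Sex-Distorter Editing Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the design and evaluation of synthetic
    CRISPR/Cas9 sex distorters in species with XY sex determination. Discovers
    candidate X-linked repeat targets from raw sexed short-read and long-read
    sequencing data using a k-mer census and the chromosome quotient statistic,
    screens candidate gRNA protospacers for off-target potential against
    autosomal and Y-derived long reads, quantifies editing outcomes from
    amplicon deep sequencing of tandem repeat clusters (intact-target
    fractions, allele spectra, cleavage-resistant alleles, coding effects),
    and computes sex-ratio and developmental survival statistics from genetic
    crosses. Includes a seeded synthetic-data generator that emulates a
    diploid-female/hemizygous-male genome with X-linked repeat clusters,
    sexed read sets, cut-repair editing regimes and amplicon sequencing, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
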