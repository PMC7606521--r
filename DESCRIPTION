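Package: epimsfs
Title: Population Epigenetics from Methylome Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of DNA methylation treated as
    a hypermutable heritable polymorphism. Aggregates per-cytosine bisulfite
    calls into 100-bp tile methylation levels, calls discrete epigenotypes via
    normal-mixture thresholds, builds methylome site frequency spectra (mSFS),
    and infers forward/backward epimutation rates and selection coefficients
    by Metropolis-Hastings MCMC under the Wright-type stationary density for
    hypermutable loci. Includes genomic-interval permutation statistics
    (sweep-window outlier merging, overlap enrichment, DMR-SNP linkage
    disequilibrium) and a synthetic-data generator so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    data.table,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
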