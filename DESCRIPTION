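Package: methylcomp
Title: Technology-Independent Cell Type Composition Estimation for DNA
    Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cell type composition of heterogeneous DNA
    methylation samples (such as whole blood) in a platform-agnostic way.
    Methylation is summarized over genomic regions in which each cell type
    is clearly methylated or unmethylated; these binary region states are
    biology-driven latent classes shared across technologies, while
    platform-dependent random effects absorb the systematic shift and
    attenuation that differ between microarray and bisulfite-sequencing
    measurements. Model fitting uses an EM algorithm whose M-step solves a
    simplex-constrained quadratic program for the cell proportions. The
    package also provides the classical reference-based constrained
    least-squares estimator, a deterministic differentially-methylated-region
    caller to build the region-state matrix from sorted-cell reference data,
    readers for beta-value tables and Bismark coverage files, and a
    two-platform simulation framework for benchmarking estimators by
    cell-type-specific RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    quadprog,
    stats,
    utils
Suggests:
    mvtnorm,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
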