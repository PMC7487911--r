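Package: dcmscan
Title: Composite Selection-Signature Scans with the DCMS Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome scan for signatures of selection in multi-population
    SNP panels. Five per-SNP population-genetic statistics (Weir-Cockerham
    FST, nucleotide diversity, binned Tajima's D, and Garud's H1/H12
    haplotype homozygosity over sliding windows) are converted to
    fractional-rank one-tailed p-values and combined into the de-correlated
    composite of multiple signals (DCMS), weighted by a minimum covariance
    determinant robust correlation matrix. Composite scores are calibrated
    with an intercept-only Huber fit, converted to upper-tail p-values and
    Benjamini-Hochberg q-values, and resolved into candidate regions with
    distance-ranked gene annotations. A forward-in-time Wright-Fisher
    simulator with hard sweeps generates phased panels with known truth so
    the whole pipeline can be exercised and validated without external
    genotype data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
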