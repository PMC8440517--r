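Package: famcond
Title: Conditional Direct and Indirect Genetic Effects from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Partitions marginal GWAS effect sizes into conditional direct
    (offspring) and indirect (maternal, paternal, sibling-mediated)
    components using only summary results statistics. Implements the exact
    linear transformation of paired own/offspring GWAS estimates, a
    multi-group structural equation model fitted to covariance matrices
    reconstructed from summary statistics, and an overlap-aware solver in
    the style of Genomic SEM whose per-variant sampling covariance is built
    from cross-trait LD score regression intercepts. Includes LD score
    regression (univariate and bivariate intercepts, genetic correlation,
    sample-overlap estimation), summary-statistics harmonization, locus
    counting and heterogeneity tests, and a family-trio simulator that
    generates GWAS inputs with known truth and configurable sample overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
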