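Package: elgwas
Title: Energy-Landscape Subtyping of Case-Control GWAS Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers latent disease subtypes from case-control genotype data
    by fitting a pairwise maximum-entropy (Ising) model to binarized,
    coefficient-weighted principal-component scores of GWAS association
    signals, and analysing the resulting energy landscape with
    disconnectivity graphs. Includes PLINK-style marker and sample quality
    control with LD pruning, covariate-adjusted logistic association,
    exact contingency-table and Hardy-Weinberg tests, downstream subtype
    statistics (biomarker comparisons with FDR, eQTL regression), a
    feed-forward neural-network subtype predictor, and a synthetic-cohort
    generator for end-to-end validation without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr
Config/testthat/edition: 3
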