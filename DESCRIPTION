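Package: reboundomics
Title: Rebound Multi-Omics Analysis of Pregnancy-Induced T-Cell Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for longitudinal paired
    methylation/expression cohorts sampled through and after pregnancy.
    Implements probe and low-count gene filtering, beta/M transformation,
    trimmed-mean-of-M-values normalization, precision-weighted generalized
    least squares with a donor-block consensus correlation and
    empirical-Bayes moderated statistics, classification of "rebound"
    features (changed in the 3rd trimester, reversed post-partum) shared
    between disease and control groups, DIAMOnD seed-connector expansion of
    rebound genes on a protein-protein interaction network, cross-omics
    module intersection, and Fisher/hypergeometric enrichment with
    background correction, GWAS SNP-to-gene mapping and a CpG-gene
    correlation-conservation test. Includes a synthetic-cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
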