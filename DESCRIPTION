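Package: gainscan
Title: Genomic and Environmental Dissection of Long-Term Genetic Gain in Maize Era Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-decade genetic progress in maize breeding
    panels: simulation of era panels and multi-environment trials with known
    ground truth, genotype quality control and relationship matrices,
    environmental scenario typing by partitioning around medoids, genetic-gain
    estimation and genotype-by-environment variance partitioning, constrained
    Gaussian Bayesian-network analysis of trait mediation with BGe scoring and
    bootstrap model averaging, kinship-controlled temporal genome scans and
    covariance-standardised allele-frequency differentiation for regions under
    selection, permutation tests of colocalization enrichment between selection
    signatures and QTL intervals, and scenario-conditional prediction of QTL
    allelic effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
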