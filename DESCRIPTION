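Package: qtsmap
Title: Full-Model QTS Association Mapping with Epistasis and
    Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Association mapping of quantitative trait SNPs (QTSs) under a
    full genetic model with additive and dominance main effects, four digenic
    epistasis classes (additive-additive, additive-dominance,
    dominance-additive, dominance-dominance), and random environment and
    gene-environment interaction effects, estimated by Gibbs sampling.
    Includes SNP quality control and LD pruning/decay summaries, generalized
    multifactor dimensionality reduction (GMDR) prescreening, one- and
    two-dimensional genome scans with permutation-based experiment-wise
    thresholds, broad-sense heritability partitioning into per-effect and
    per-class components, prediction of superior pure-line and hybrid
    genotypes (general and environment-specific), subpopulation
    stratification checks, and a seeded synthetic-data generator emulating a
    multi-environment germplasm panel design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
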