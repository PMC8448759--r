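Package: annonet
Title: Annotation-Guided Sparse Neural Networks for Genotype-to-Phenotype
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds neural networks whose connections are defined exclusively
    by biological annotations (variant-to-gene, gene-to-pathway hierarchy,
    gene-to-tissue expression), trains them on genotype dosage matrices to
    predict binary or quantitative phenotypes, and interprets every learned
    weight as a biological effect via path-product relative importance.
    Includes a liability-threshold phenotype simulator with tunable
    heritability, polygenicity and two-SNP interaction architectures, the
    theoretical AUC ceiling implied by heritability, an L1-regularized
    logistic baseline, randomly-connected comparator networks, genotype
    file conversion (VCF and PLINK-raw style), zero-variance filtering and
    kinship-aware cohort splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
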