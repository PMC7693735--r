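Package: gmdrprs
Title: Gene-Gene Interaction Screening and Polygenic Risk Scores for
    Case-Control Cohorts via Generalized Multifactor Dimensionality
    Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for candidate-SNP case-control
    studies: per-SNP and per-sample quality control (minor allele
    frequency, call rate, Hardy-Weinberg equilibrium, heterozygosity),
    covariate-adjusted logistic association scans with a hard p-value
    selection gate, linkage-disequilibrium pruning of dosage r-squared,
    generalized multifactor dimensionality reduction (GMDR) search for
    multi-locus genotype interactions scored by cross-validated balanced
    accuracy, construction of unweighted risk-allele-count polygenic risk
    scores (PRS) with tertile or fixed categorisation, and stratified
    PRS-by-environment interaction analysis in multiplicative logistic
    models. Includes a synthetic cohort generator (Hardy-Weinberg
    genotypes, latent-Gaussian linkage disequilibrium, penetrance-table
    epistasis, gene-environment effects) so every stage is testable
    without restricted cohort data, plus readers and writers for PLINK
    .raw dosage text, VCF, and CSV phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
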