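Package: kbscreen
Title: Knowledge-Based SNP Screening with Two-Stage Permutation Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacogenomic adverse-event association pipeline combining
    knowledge-based SNP pre-filtering by Gene Ontology term membership,
    Hardy-Weinberg and minor-allele-frequency quality control, two-stage
    case-control screening with two-sided Fisher's exact tests under allele,
    dominant and recessive genetic models, a family-wise min-p permutation
    correction that replays both screening stages on label-shuffled cohorts,
    Benjamini-Hochberg q-values, tied-rank Spearman covariate scans, and
    logistic-regression model selection by AIC and ROC/AUC. Includes a
    synthetic cohort generator emulating the cohort structure the analysis
    assumes (Hardy-Weinberg genotypes, GO-annotated gene structure, a logistic
    phenotype model, and a nested monotherapy subset) so that every stage is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
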