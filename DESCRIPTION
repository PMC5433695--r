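Package: sibscreen
Title: Sib-Pair Heritability and Genotype Risk Screening for Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two complementary sib-pair analyses of a binary
    disease trait, developed around type 1 diabetes family data.
    Estimates narrow-sense heritability by Haseman-Elston regression of
    squared sib-pair phenotype differences on genome-wide
    identity-by-descent sharing, with an observed-to-liability scale
    transformation and stratified bootstrap standard errors.  Fits and
    evaluates a nine-feature logistic model that scores a sibling's
    disease risk from three HLA-region SNP genotypes of the proband and
    the sib, with ROC/AUC machinery and prevalence-dependent screening
    metrics (PPV/NPV).  Reads and writes PLINK '.genome'-style IBD
    tables, and includes a liability-threshold simulator of sib-pair
    cohorts (IBD sharing, Mendelian 3-SNP genotypes, affected-proband
    ascertainment) so both analyses can be exercised end to end without
    access to consortium data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
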