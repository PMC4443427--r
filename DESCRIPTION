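Package: hlaFineMap
Title: Fine-Mapping of MHC Association Signals from HLA Allele Dosages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for fine-mapping disease associations across the major
    histocompatibility complex from imputed SNP, classical HLA allele and
    amino-acid residue dosages. Implements expansion of classical-allele
    dosages into per-position amino-acid residue markers, omnibus
    multi-allelic likelihood-ratio tests, stepwise conditional association
    analysis with principal-component covariates, post-imputation dosage
    quality control, HLA-stratified epistasis tests for candidate variants,
    and a case-control cohort simulator with configurable allele effect
    sizes and stratum-restricted interactions for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
biocViews: Genetics, SNP, GenomeWideAssociationStudy, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'AllClasses.R'
    'data_io.R'
    'aa_expansion.R'
    'qc.R'
    'assoc_core.R'
    'stepwise.R'
    'epistasis.R'
    'synthetic_data.R'
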