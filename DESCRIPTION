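Package: famgwas
Title: Family-Based Mixed-Model Association for Longitudinal Lipid Traits
    and Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-based genome-wide association testing built on
    variance-component mixed models. Implements (i) a bivariate longitudinal
    mixed model for two correlated traits (triglycerides and HDL cholesterol)
    measured at four visits, with a Markov-product temporal correlation,
    genetic and environmental cross-trait correlations, a Kronecker-structured
    covariance evaluated by simultaneous diagonalization, and a 2-df
    likelihood-ratio SNP test; and (ii) a Henderson mixed-model F-test for
    association of single SNPs and multi-SNP genomic regions with a
    treatment-response phenotype, with EM-REML variance-component estimation
    and BLUPs. Includes pedigree kinship computation, genotype and phenotype
    input with SNP-level quality control, log-log phenotype transformation and
    kinship-aware imputation, genic/intergenic region construction with LD
    pruning, Benjamini-Hochberg reporting, and a full synthetic family-data
    simulator (pedigrees, Mendelian gene dropping, model-exact phenotypes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
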