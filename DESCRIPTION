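Package: hisplexr
Title: Imputation-Aware HIrisPlex-S Pigmentation Phenotyping from Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting eye, hair and skin colour from diploid
    genotypes with the 41-marker HIrisPlex-S system, aimed at low-coverage
    and imputed data. Translates reference-based VCF genotypes into the
    strand-aware probe allele counts the HIrisPlex-S assay reports, computes
    the 14 trait probabilities with a multinomial-logistic model, classifies
    the three pigmentation traits with a transparent, data-driven rule set,
    builds the genomic windows used as imputation targets, and provides the
    validation machinery (total and opposite genotype error, replicate
    phenotype concordance, red-hair confusion rates, reference-bias
    flagging) together with a fully synthetic haplotype-panel simulator and
    a naive panel-based imputer for testing the whole workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
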