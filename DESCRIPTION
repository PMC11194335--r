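Package: mxegp
Title: Multi-Environment Genomic Prediction from Pooled Allele Frequencies
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for pool-genotyped plant accessions across
    multiple field environments.  Provides quality control, imputation and
    standardisation of accession-by-marker allele-frequency panels, genomic
    relationship matrices, per-environment BLUE/BLUP extraction from
    incomplete-block and partially replicated field trials, and GBLUP models
    fitted by Gibbs sampling in three flavours: single-environment,
    across-environment (shared marker effects), and marker-by-environment
    interaction (shared plus environment-specific marker effects).  Includes
    CV1/CV2 and leave-group-out cross-validation, predictive-ability and
    prediction-bias metrics, marker-number and training-fraction sweeps,
    cross-population validation, and a synthetic-data generator with
    population structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
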