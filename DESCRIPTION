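Package: crfgwas
Title: Conditional Random Field Association Testing for Structured
    Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide association testing for binary phenotypes that
    corrects for population structure, family structure and cryptic
    relatedness by modelling all phenotypes jointly as a fully connected
    pairwise conditional random field with identity-by-state (IBS)
    genetic similarities as edge weights.  Parameters are estimated by
    convex pseudo-likelihood maximisation; per-SNP significance is
    assessed with a Wald test using a robust (sandwich) variance
    estimator.  Includes IBS kinship computation, genotype filters and
    PLINK text readers, a structured-population synthetic-data generator
    (Balding-Nichols subpopulations plus family blocks, GLMM-sampled
    phenotypes), and calibration/power evaluation utilities (genomic
    inflation factor, QQ data, ROC/AUC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
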