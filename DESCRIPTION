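Package: strigapanel
Title: Genetic Analysis of Striga Resistance in Multi-Environment Maize Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for the quantitative-genetic analysis of
    parasitic-weed (Striga hermonthica) resistance in inbred maize panels
    evaluated in multi-environment alpha-lattice trials. Provides stage-1
    phenotypic mixed models with REML variance components, entry-mean
    heritability and derivation of the area under the Striga number progress
    curve (AUSNPC); marker quality control, VanRaden genomic relationships,
    principal components and linkage-disequilibrium decay with an
    effective-number-of-tests significance threshold; mixed-linear-model
    genome-wide association scans with structure and kinship correction
    (P3D); GBLUP genomic prediction within and across environments with
    genotype-by-environment interaction under CV0/CV1/CV2 cross-validation;
    an item-based collaborative-filtering predictor over the line by
    trait-environment matrix; and a synthetic-data generator that emulates
    the trial design for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
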