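Package: gbsblup
Title: Genomic Prediction from Genotyping-by-Sequencing Read Depths in Polyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for polyploid species genotyped by sequencing
    without allele dosage calls. Builds genomic relationship matrices from
    read-depth "continuous genotypes" under naive, diagonal-debiased, and
    Beta-Binomial overdispersion scalings; fits single- and multi-trait GBLUP
    with permanent-environment effects; estimates variance components by
    EM-REML; derives heritability, repeatability, and genetic correlations;
    and validates genomic breeding values by half-sib family cross-validation,
    forward prediction, and Legarra-Reverter statistics. Includes a simulator
    of hexaploid GBS read data with half-sib family structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
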