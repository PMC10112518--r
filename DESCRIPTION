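Package: loadgp
Title: Multi-Kernel GBLUP Genomic Prediction with Deleterious Mutation Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and prediction machinery for studying how knowledge of
    deleterious mutations can improve genomic prediction in clonally propagated
    crops. Provides a two-population synthetic genotype generator
    (Balding-Nichols divergence model), quantitative trait simulation with
    gamma-distributed QTL effects and truncated-normal dominance, additive
    (VanRaden) and dominance (zero-mean heterozygosity coding) genomic
    relationship matrices with optional per-site functional weights,
    restricted-maximum-likelihood estimation for multi-kernel linear mixed
    models with BLUP prediction of masked individuals, deleterious-site
    classification with per-clone derived-allele burden, conservation
    classifier weights under leave-one-chromosome-out, and cross-population /
    k-fold evaluation of prediction accuracy and top-k clone recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
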