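Package: ovitraits
Title: Feed Efficiency, Methane and Body Composition Genetics for Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct feed-efficiency, greenhouse-gas and body
    composition phenotypes for growing sheep from raw records, and to
    estimate their genetic parameters under pedigree-based animal models.
    Builds residual feed intake (RFI) from automated-feeder event logs and
    biweekly liveweights, daily methane and carbon dioxide emission traits
    from portable accumulation chamber (PAC) concentration profiles with a
    lot-mean scaling correction, and carcass and visceral tissue masses from
    Hounsfield-unit segmentation of computed tomography slice stacks.
    Includes a pedigree module (numerator relationship matrix, inbreeding,
    sparse A-inverse by Henderson's rules), a REML engine for univariate and
    bivariate animal models with maternal and permanent-environment effects,
    and a synthetic cohort generator with known ground truth for validating
    every pipeline stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
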