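Package: famgxe
Title: Family-Based Polygenic Risk Score by Risk Factor Interaction Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for family-based assessment of interactions between a
    multiplicative polygenic risk score (PRS) and non-genetic risk factors
    in young-onset breast cancer studies. Implements PRS construction from
    risk-allele dosages, pseudo-sibling genotypes from case-parent trios,
    the four matched-set designs that cross genotype and exposure sources
    within a family, conditional logistic regression with exact
    Newton-Raphson maximisation of the stratified likelihood,
    ratio-of-odds-ratios interaction estimation with Wald inference, and a
    calibrated simulator of ascertained nuclear families so that every
    stage of the pipeline is verifiable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
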