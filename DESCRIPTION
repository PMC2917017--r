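Package: brcapath
Title: Pedigree-Based BRCA1/BRCA2 Carrier Probabilities Using Breast
    Tumour Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mendelian risk prediction for familial breast and ovarian
    cancer in which breast cancer subtypes (oestrogen-receptor status,
    triple-negative status, basal cytokeratin expression) are modelled as
    distinct disease end points. Genotype-specific subtype incidences are
    derived by constraining a major-gene (BRCA1/BRCA2) plus hypergeometric
    polygene susceptibility model to carrier and population incidence
    curves, and Bayesian mutation-carrier probabilities are computed from
    full pedigrees by exact Elston-Stewart peeling, combining family
    history, tumour marker panels and genetic test results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
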