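Package: mutdfe
Title: Nonparametric Bayesian Estimation of the Distribution of Fitness
    Effects in Mutagenized Plant Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the first two moments of the distribution
    of fitness effects (DFE) of induced mutations from field fitness data on
    selfed plant mutation lines.  Provides a generative simulator of the
    mutagenesis breeding design (Poisson mutation numbers, Mendelian dosage
    segregation over selfing generations, logistic survival, log-normal
    biomass), exact compound-Poisson moment machinery for the mutational
    deviation and its line/subline/individual covariance decomposition, a
    zero-inflated hierarchical Bayesian model fitted by mean-field
    variational inference, derived evolutionary quantities (mutational
    variance and heritability, among-accession genetic variance,
    generation-scale extrapolations), and classical descriptive statistics
    (group summaries, Dunnett-type many-to-one comparisons, Fisher's exact
    test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    multcomp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
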