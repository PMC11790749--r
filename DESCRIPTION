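Package: biftwin
Title: Bifactor Twin Modeling of Genetic and Environmental Dimensionality
Version: 1.0.0
Authors@R: person("biftwin", "maintainers", email = "maintainers@biftwin.org", role = c("aut", "cre"))
Description: Fits bifactor common-pathway and bifactor independent-pathway
    ACE structural equation models to monozygotic/dizygotic twin-pair item
    data using full-information maximum likelihood, compares ACE/AE/CE/E
    submodels via likelihood-ratio tests and RMSEA/CFI/AIC/BIC, and
    bootstraps confidence intervals. Also provides the phenotypic bifactor
    workflow (Direct Schmid-Leiman estimation; omega-hierarchical, H-index
    and explained-common-variance reliability indices) and a twin-data
    simulator for ordinal symptom scales.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    numDeriv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
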