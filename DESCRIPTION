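Package: cuspevol
Title: Comparative Phylogenetics of Tooth Complexity and Diet Evolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the macroevolution of discrete dental
    characters and diet on time-calibrated phylogenies with fossil tips.
    Implements Mk model fitting with Akaike-weight transition-matrix
    averaging, marginal ancestral state reconstruction, stochastic
    character mapping by uniformisation, Bayesian tests of correlated
    evolution between binary traits with steppingstone marginal
    likelihoods and log Bayes factors, branch-level transition counting
    (independent originations, path-paired changes, time-binned lineage
    dynamics), open-outline geometric morphometrics by discrete cosine
    transform with ordinary and phylogenetic PCA, permutation
    phylogenetic MANOVA and discriminant analysis, a binary-state
    speciation-extinction (BiSSE) likelihood and fitter, nonparametric
    group tests with bootstrap effect sizes, and a synthetic-study
    generator producing trees, correlated characters, and diet-linked
    tooth outlines with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    MASS,
    optparse
Config/testthat/edition: 3
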