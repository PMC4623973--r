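Package: phlinkage
Title: Constant-pH Monte Carlo and Proton-Linkage Analysis of Ligand Binding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale constant-pH Metropolis Monte Carlo with replica
    exchange in the pH dimension over configurable multi-site protonation
    models, together with the analysis stack used to interpret such
    simulations: exact partition-function (semi-grand ensemble) oracles,
    Hill-equation estimation of microscopic pKa values and Hill
    coefficients, and Wyman binding-polynomial computation of pH-dependent
    protein-ligand binding free energy profiles, including fixed
    protonation-state error scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
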