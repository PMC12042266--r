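Package: hydrolyzer
Title: Template-Driven Hydrolysis Enumeration and Reaction Free-Energy
    Prediction with Reaction-Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Enumerates hydrolysis reactions of organic molecules by
    functional-group templates under neutral, acid-catalyzed (protonated,
    +1) and base-catalyzed (hydroxylated, -1) schemes, with full
    explicit-hydrogen atom mapping and pH-dependent stoichiometry
    (hydronium / hydroxide co-products).  Builds union reaction graphs
    holding product-minus-reactant difference features over mapped atoms
    and bonds plus a global node, and trains a gated graph-convolution
    neural network on them to predict hydrolysis Gibbs free energies
    (kcal/mol).  Includes a synthetic labelled-reaction generator with an
    additive bond-increment surrogate energy, dataset readers/writers,
    evaluation reports (MAE, RMSE, R-squared, endergonic/exergonic sign
    accuracy, per-group error tables) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
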