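Package: avgmodel
Title: Averaging-Model Analysis of High-Order Genetic Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of quantitative phenotypes measured over exhaustively
    combinatorial active/inactive genotypes of a multi-gene system. Implements
    three general linear model parameterizations of the genotype cell means --
    the classical additive (ANOVA-with-interaction) model, the network
    reconstitution (NR) model, and the averaging model, in which every
    interaction coefficient is the deviation of a genotype from the average of
    the genotypes with one fewer active gene. Provides exact coefficient
    solving on complete genotype lattices, least-squares and nested
    mixed-effects fitting with confidence intervals and Holm correction,
    Benjamini-Hochberg gene-inclusion screening with genotype bundling, model
    reduction, Monte-Carlo coefficient-stability studies, a mechanistic
    network evaluator, and a synthetic replicated-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    nlme
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
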