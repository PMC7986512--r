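Package: symdisp
Title: Quantifying Fish-Mediated Dispersal of Coral Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the dispersal of coral endosymbionts
    (family Symbiodiniaceae) in the feces of coral reef fishes. Converts
    hemocytometer technical-replicate counts with trypan-blue live/dead
    scoring into cell densities per ml of source material and per gram of
    feces; compares genus-level ITS2 amplicon communities with Bray-Curtis
    dissimilarities, PERMANOVA (with pairwise tests and Benjamini-Hochberg
    correction), multivariate dispersion tests and rarefaction; estimates
    reef-scale symbiont flux with a bootstrap of the product T = gSWCF
    (egestions per day x pellet length x fecal linear density x live cells
    per gram x fish density); and provides the univariate field statistics
    (Kruskal-Wallis with Dunn post-hoc tests, coral-cover ANOVA with
    assumption checks, prevalence and culture summaries). A synthetic-data
    generator with known ground truth emulates the statistical structure of
    the field study (guild-structured lognormal cell densities spanning
    seven orders of magnitude, Dirichlet-multinomial genus compositions,
    Poisson egestion and transect counts) so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
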