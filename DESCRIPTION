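Package: tzdqsar
Title: QSAR Modelling of Thiazolidine-2,4-dione Lipoxygenase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and validates quantitative structure-activity relationship
    (QSAR) models for the soybean lipoxygenase inhibition of nineteen
    5-arylidene-thiazolidine-2,4-diones. Computes the three model descriptors
    from structure alone (the Kier-Hall electrotopological MAXDP, the
    mass-weighted 3D-MoRSE signal Mor29m, and the WHIM directional symmetry
    G2u), selects descriptor subsets by a genetic algorithm with an exhaustive
    oracle, fits ordinary least-squares models, and reports the full internal
    validation suite (Q2 leave-one-out and leave-more-out, PRESS, Y-scrambling,
    Lin's concordance correlation, the K multivariate correlation index) plus
    a leverage-based applicability domain (Williams plot). A synthetic-data
    generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (the obabel executable) for structure parsing,
    2D layout and force-field minimisation.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
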