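Package: fermscreen
Title: Kinetic Analysis and Relative-Performance Ranking for Yeast
    Fermentation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing diauxic (glucose-then-xylose) yeast
    fermentation time courses from strain-screening experiments:
    extraction of kinetic parameters (sugar uptake rates, ethanol
    productivities, yields per initial sugar, specific growth rates,
    lag and diauxic-lag times), multi-environment strain ranking by
    Relative Performance Index (RPI) with dispersion diagnostics,
    factorial ANOVA with Student-Newman-Keuls compact letter displays,
    and a seeded mechanistic simulator of diauxic fermentations with
    ethanol-repressed xylose induction and acetic-acid and furfural
    inhibition, so that every stage of the pipeline can be exercised
    against data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
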