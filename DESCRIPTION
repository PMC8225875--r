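Package: hsgain
Title: Genetic Gain Modelling for Half-Sib Family Recurrent Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic modelling of genetic gain in half-sib
    (HS) family breeding programs for outcrossing forage species. Provides a
    deterministic engine predicting per-cycle gain for five HS breeding
    strategies that integrate genomic selection (rrBLUP genomic estimated
    breeding values) and phenomics-based phenotyping; REML estimation of
    variance components and family-mean heritability from multi-location,
    multi-season, multi-year HS progeny trials; a cost-per-percent-gain model;
    a gamete-level stochastic simulator of multi-cycle recurrent selection on a
    multi-chromosome genetic map; and synthetic-data generators for mock trials
    and founder populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
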