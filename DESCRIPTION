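Package: dispscan
Title: Genome Scans for Phenotypic Dispersion Loci in F2 Intercrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps variance quantitative trait loci (vQTL) in F2 intercross
    cohorts by regressing per-individual phenotypic dispersion -- the absolute
    externally Studentized residual from a covariate model -- on marker
    genotype with left-bounded (truncated or censored) Gaussian Tobit models.
    Provides joint Wald tests per marker, additivity and dominance contrasts
    with Griffing's potence ratio, architecture labelling, Benjamini-Hochberg
    false discovery rate control with a nominal hard floor, cross-cohort
    consensus locus grouping, and a synthetic F2 cohort generator with a
    Haldane map function so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
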