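Package: meltscreen
Title: Proteome-Wide Enzyme Substrate Screening from Thermal Shift Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for four-arm thermal proteome profiling
    experiments (vehicle / cosubstrate / enzyme / enzyme+cosubstrate) aimed
    at identifying enzyme substrates by their treatment-specific melting
    temperature shifts. Reads wide protein quantification tables, normalizes
    melting curves to the bulk proteome, fits per-protein sigmoid melting
    models, computes treatment contrasts on melting temperatures, classifies
    cosubstrate binders, enzyme substrates and enzyme interactors under
    configurable criteria, estimates the screen-wide false discovery rate by
    permutation, and ranks candidates with OPLS-DA variable-importance
    scores. A synthetic-experiment generator with planted ground truth
    supports benchmarking, and helpers cover the orthogonal validation
    computations (phosphopeptide filtering, label-free pulldown
    normalization and imputation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
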