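Package: icongem
Title: Integration of Gene Co-Expression Networks into Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts condition-specific metabolic flux distributions by
    integrating a gene co-expression network into a genome-scale metabolic
    model. Reaction upper bounds are set from transcript abundance through
    gene-protein-reaction rules (E-flux style), and fluxes are chosen by a
    quadratic program that maximizes the co-activation of reaction pairs
    whose genes are connected in the co-expression network, subject to
    steady-state mass balance and a biomass requirement. Includes template
    model construction with reversible-reaction splitting, correlation
    network thresholding by scale-free topology fit, flux-variability
    flexibility analysis, topological-overlap module detection, and
    accuracy scoring of predictions against measured fluxes with the
    uncentered Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    mclust,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
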