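Package: thermodiv
Title: Temperature Dependence of Soil Microbial Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continental-scale analyses linking soil microbial
    diversity to environmental temperature under the metabolic theory of
    ecology. Provides alpha-diversity estimators (Chao1, Shannon, inverse
    Simpson), phylogenetic community structure (Faith PD, abundance-weighted
    mean pairwise distance, net relatedness index with phylogeny-shuffle
    nulls), distance-matrix statistics (Mantel, partial Mantel, BioENV),
    Boltzmann-Arrhenius activation-energy fitting with AIC model selection,
    rarefaction and site-pooling of OTU count tables, and a synthetic
    multi-site metacommunity generator with known activation energies for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
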