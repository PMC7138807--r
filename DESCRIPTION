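Package: soilbiogeo
Title: Biogeography and Co-Occurrence Analysis of Soil Microbiome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of continental-scale soil
    microbiome surveys from OTU count tables: rarefaction, alpha and beta
    diversity (Bray-Curtis, weighted UniFrac), geographic distance-decay of
    community similarity, environment-community permutation statistics
    (Mantel, PERMANOVA, ANOSIM, constrained analysis of principal
    coordinates), core-microbiome detection with partitioned Bray-Curtis
    contribution, and Spearman co-occurrence networks with Erdos-Renyi null
    ensembles and betweenness-based keystone identification. Includes a
    synthetic community generator with planted spatial decay, environmental
    responders, core prevalence and correlated guilds so every stage can be
    validated against known ground truth.
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
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
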