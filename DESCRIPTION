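Package: metahub
Title: Metacommunity-Scale Plant-Fungus Association Networks and Hub Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds local and metacommunity-scale bipartite networks of
    below-ground plant-fungus associations from sample-by-OTU read-count
    tables, scores fungal OTUs by (standardized) betweenness centrality, and
    classifies them as metacommunity hubs, metacommunity connectors, local
    hubs, or peripherals. Includes the supporting preprocessing steps
    (rare-association filtering, rarefaction, species-level matrix
    conversion), interaction-specificity (d') scoring, community-composition
    statistics (Bray-Curtis, PERMANOVA, PERMDISP) implemented from their
    definitions, and a synthetic metacommunity generator with planted hubs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
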