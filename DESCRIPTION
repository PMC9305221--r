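Package: batnet
Title: Weighted Bipartite Bat-Plant Interaction Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing weighted bipartite ecological interaction
    networks, built around molecular (faecal DNA) bat-plant diet data.
    Implements the weighted nestedness index WNODF, Barber bipartite
    modularity maximised with the DIRTLPAwb+ label-propagation algorithm,
    within-module nestedness for compound topologies, the vaznull and
    module-conserving null models with z-scores, the decomposition of
    interaction dissimilarity into rewiring and species-turnover components,
    Chao1 sampling completeness and individual-based rarefaction, and a
    synthetic-network generator with planted modular structure for offline
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
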