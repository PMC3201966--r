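Package: trophicnets
Title: Food Web Topology and the Topological Determinants of Parasite
    Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the topological analysis of binary predator-prey
    food webs and the prediction of within-host parasite diversity from
    network position. Implements web-level summary statistics (species
    richness, links, linkage density, directed connectance), cumulative
    degree distributions with exponential / power-law / truncated
    power-law model selection by AICc, nestedness temperature with a
    row-column-fill (Ce) null ensemble and relative nestedness, species
    centralities (eigenvector, betweenness, closeness) and a continuous
    MINRES core/periphery model, a directed group (block) model fitted by
    likelihood and AIC with simulated-annealing partition search, a
    parasite life-cycle overlay enforcing stage-wise host viability and
    inferring trophic links from parasitological records, and regression
    tree / random forest models of per-host parasite richness with two
    variable-importance measures. A synthetic-data module generates food
    webs with planted group structure and degree heterogeneity, plus
    parasite assemblages whose host choice is biased toward central
    hosts, so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    vegan,
    minpack.lm,
    rpart,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
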