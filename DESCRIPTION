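Package: treeweb
Title: Tree-Fungal Bipartite Co-Occurrence Networks and Fungal Specialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tree-fungal bipartite co-occurrence networks from soil
    fungal OTU tables collected in a broken-stick forest-diversity planting
    design, and analyses fungal specialization across tree diversity levels.
    Implements the full pipeline: OTU table preprocessing (rare-OTU removal,
    rarefaction, abundance pruning, incidence transform), enumeration of
    balanced subsampling combinations over the planting design, threshold-based
    web construction with network statistics (connectance, generality,
    Stone-Roberts C score, NODF nestedness, Barber bipartite modularity,
    shared partners, alpha diversity), fixed-margin (Patefield) null models,
    phi-coefficient specialization analysis with functional-guild contrasts,
    rank statistics (Kruskal-Wallis with Siegel-Castellan post hoc, Wilcoxon
    rank-sum, Holm adjustment), and a synthetic-data generator with planted
    specialist/generalist structure for validation.
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
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
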