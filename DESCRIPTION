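Package: methprior
Title: Methylation-Weighted Protein Interaction Networks for Cancer Gene
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a weighted human protein-protein interaction network in
    which each retained edge carries the Pearson correlation of the two genes'
    DNA methylation profiles, screened by a matrix-permutation significance
    rule. From a set of seed genes with experimentally established aberrant
    methylation it extracts the cancer-associated subnetwork (seeds plus their
    direct interactors), characterises its topology (degree distribution and
    power-law exponent, clustering coefficient, shortest-path statistics)
    against three randomization null models with Wilcoxon rank-sum tests and
    Benjamini-Hochberg correction, prioritizes candidate genes by a
    neighborhood-weighting score compared against per-candidate permutation
    nulls, and screens differentially expressed genes with a
    resampling-stabilized SAM score. A synthetic-data generator with planted
    correlated edges, seed neighborhoods and differential expression makes the
    whole pipeline testable without external downloads.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
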