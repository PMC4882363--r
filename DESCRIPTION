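Package: toxbasket
Title: Market-Basket Mining of Atom-Pair Toxicophores for Acute Aquatic Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines probabilistic association rules that link topological
    atom-pair substructures to GHS acute aquatic toxicity categories derived
    from 96-h fathead minnow LC50 data. Provides a from-scratch Apriori
    frequent-itemset miner with exact rational support arithmetic, minimal
    toxicophore (structural alert) extraction from rule redundancy, rule-based
    classification of new structures with a Tanimoto nearest-neighbour
    surrogate fallback, stratified k-fold cross-validation, and a synthetic
    dataset generator with planted category-associated motifs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
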