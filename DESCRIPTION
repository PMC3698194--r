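Package: hymeflight
Title: Phylogenetic Comparative Analysis of Flight Morphology in
    Central-Place Foraging Hymenoptera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing how food-load manipulation ability relates
    to flight morphology (flight muscle ratio and wing loading) across
    bees and wasps while accounting for shared ancestry.  Provides
    phylogenetic generalized least squares with maximum-likelihood
    estimation of Pagel's lambda (including a two-group heteroscedastic
    extension and likelihood-ratio tests), marginal ancestral-state
    reconstruction of a binary character under the symmetric one-rate
    Markov (Mk1) model with the two-log-unit decision rule, Fitch/Hartigan
    parsimony counting of character origins, flight-biomechanics indices
    and load-lifting capacity prediction, allometric scaling fits, seeded
    generators for trees and lambda-structured traits, and an end-to-end
    analysis pipeline with a bundled 28-species dataset and reference
    phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    graphics,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
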