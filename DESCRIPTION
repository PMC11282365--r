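Package: chronograft
Title: Mine Node Ages from Published Chronograms and Date Tree Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover, summarize and reuse divergence-time estimates
    from a local database of published chronograms. Taxon names are
    standardized against a pluggable taxonomy (synonyms, fuzzy matching),
    chronograms sharing at least two query taxa are pruned and stored as
    patristic distance matrices, and node ages are mapped onto a chosen tree
    topology by congruification. Per-node age summaries become secondary
    calibrations, filtered for ancestor-descendant conflicts, and a dated
    summary chronogram is produced with a BLADJ-style even-spacing algorithm.
    Includes grove detection for supertree construction, a variance-minimizing
    super-distance-matrix summary, and leave-one-study-out cross-validation of
    estimated node ages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
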