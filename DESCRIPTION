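Package: phyloM
Title: Distance-Based Detection of Phylogenetic Signal in Mixed-Type Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures and tests phylogenetic signal with the M statistic, a
    distance-based index that works uniformly on continuous traits, discrete
    (nominal or ordinal) traits, and multi-trait combinations. Trait
    dissimilarities are computed with Gower's distance; the phylogeny is
    decomposed into subtrees rooted at internal nodes with at least three
    descendant tips, each scored for whether within-branch mean trait
    distances exceed the cross-branch mean; significance is assessed by a
    right-tailed permutation test that shuffles species across the tips.
    Includes a simulation framework (pure-birth trees, Brownian-motion and
    Mk trait evolution with tunable signal intensity) and power-analysis
    drivers, plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
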