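Package: inctree
Title: Incremental Distance-Based Phylogeny Estimation with Quartet Voting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distance-based phylogeny estimation by incremental taxon
    insertion. Taxa are ordered by a breadth-first traversal of a minimum
    spanning tree of the complete distance graph and placed one at a time
    by letting short (diameter-bounded) quartet queries vote for edges of
    the growing tree, with a linear-time differential vote tally. Includes
    a constrained variant that honors leaf-disjoint constraint trees, a
    divide-and-conquer pipeline that merges neighbor-joining subset trees,
    CFN and log-det distance estimators, and sequence simulators for the
    two-state symmetric and general time reversible substitution models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
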